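<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" xmlns:cf="https://c4flux.r-lib.org/annotations" level="3" version="1" fbc:required="false">
  <model id="leaf_model" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="h" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="CO2_c" name="carbon dioxide" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" cf:id="CO2_c" cf:carbon="                 1" cf:nitrogen="                 0"/>
      <species id="CO2_h" name="carbon dioxide" compartment="h" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" cf:id="CO2_h" cf:carbon="                 1" cf:nitrogen="                 0"/>
      <species id="hnu_h" name="photon" compartment="h" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" cf:id="hnu_h" cf:carbon="                 0" cf:nitrogen="                 0"/>
      <species id="TP_h" name="triose phosphate" compartment="h" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" cf:id="TP_h" cf:carbon="                 3" cf:nitrogen="                 0"/>
      <species id="SUC_c" name="sucrose" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" cf:id="SUC_c" cf:carbon="                12" cf:nitrogen="                 0"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="bnd_1" value="          -1000000" constant="true" sboTerm="SBO:0000625"/>
      <parameter id="bnd_2" value="                 0" constant="true" sboTerm="SBO:0000625"/>
      <parameter id="bnd_3" value="                12" constant="true" sboTerm="SBO:0000625"/>
      <parameter id="bnd_4" value="           1000000" constant="true" sboTerm="SBO:0000625"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="Im_hnu" name="Im_hnu" reversible="false" fast="false" fbc:lowerFluxBound="bnd_2" fbc:upperFluxBound="bnd_4" cf:id="Im_hnu" cf:subsystem="exchange">
        <listOfProducts>
          <speciesReference species="hnu_h" stoichiometry="                 1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="Im_CO2" name="Im_CO2" reversible="false" fast="false" fbc:lowerFluxBound="bnd_2" fbc:upperFluxBound="bnd_3" cf:id="Im_CO2" cf:subsystem="exchange">
        <listOfProducts>
          <speciesReference species="CO2_c" stoichiometry="                 1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="Tr_CO2_hc" name="Tr_CO2_hc" reversible="true" fast="false" fbc:lowerFluxBound="bnd_1" fbc:upperFluxBound="bnd_4" cf:id="Tr_CO2_hc" cf:subsystem="intracellular transport">
        <listOfReactants>
          <speciesReference species="CO2_c" stoichiometry="                 1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="CO2_h" stoichiometry="                 1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="Fix_h" name="Fix_h" reversible="false" fast="false" fbc:lowerFluxBound="bnd_2" fbc:upperFluxBound="bnd_4" cf:id="Fix_h" cf:subsystem="Calvin cycle">
        <listOfReactants>
          <speciesReference species="CO2_h" stoichiometry="                 3" constant="true"/>
          <speciesReference species="hnu_h" stoichiometry="                24" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="TP_h" stoichiometry="                 1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="SucSyn_c" name="SucSyn_c" reversible="false" fast="false" fbc:lowerFluxBound="bnd_2" fbc:upperFluxBound="bnd_4" cf:id="SucSyn_c" cf:subsystem="sucrose synthesis">
        <listOfReactants>
          <speciesReference species="TP_h" stoichiometry="                 4" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="SUC_c" stoichiometry="                 1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="Ex_Suc" name="Ex_Suc" reversible="false" fast="false" fbc:lowerFluxBound="bnd_2" fbc:upperFluxBound="bnd_4" cf:id="Ex_Suc" cf:subsystem="exchange">
        <listOfReactants>
          <speciesReference species="SUC_c" stoichiometry="                 1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="Ex_Suc" fbc:coefficient="                 1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
    <annotation>
      <cf:constraints/>
    </annotation>
  </model>
</sbml>
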