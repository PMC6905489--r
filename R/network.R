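#' Configuration for the reduced leaf network generator
#'
#' The generator emulates the subsystem content of a compartmented C3 leaf
#' model: photon-driven ATP/NADPH generation with a proton-coupled ATP
#' synthase, Rubisco carboxylation/oxygenation, the complete photorespiratory
#' salvage loop across chloroplast/peroxisome/mitochondrion with glycine
#' decarboxylase releasing CO2 and NH3, the full C4 enzyme set, TCA cycle and
#' oxidative phosphorylation with an alternative oxidase, nitrate
#' assimilation, and sucrose/starch/amino-acid outputs (12/12/5.5 carbons).
#'
#' @param light_reactions,cyclic_electron_flow,calvin_cycle,photorespiration,c4_enzymes,tca_oxphos,alternative_oxidase,nitrate_assimilation,output_synthesis,transporters
#'   logical include flags per subsystem group.
#' @param h_per_atp_h,h_per_atp_m protons translocated per ATP by the
#'   chloroplastic and mitochondrial ATP synthase (curated values 3 and 4).
#' @param seed integer seed used by randomized fixture variants
#'   (see [perturb_fixture()]).
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(light_reactions = TRUE,
                           cyclic_electron_flow = TRUE,
                           calvin_cycle = TRUE,
                           photorespiration = TRUE,
                           c4_enzymes = TRUE,
                           tca_oxphos = TRUE,
                           alternative_oxidase = TRUE,
                           nitrate_assimilation = TRUE,
                           output_synthesis = TRUE,
                           transporters = TRUE,
                           h_per_atp_h = 3,
                           h_per_atp_m = 4,
                           seed = 1L) {
  structure(list(
    include = c(light_reactions = light_reactions,
                cyclic_electron_flow = cyclic_electron_flow,
                calvin_cycle = calvin_cycle,
                photorespiration = photorespiration,
                c4_enzymes = c4_enzymes,
                tca_oxphos = tca_oxphos,
                alternative_oxidase = alternative_oxidase,
                nitrate_assimilation = nitrate_assimilation,
                output_synthesis = output_synthesis,
                transporters = transporters),
    h_per_atp_h = h_per_atp_h,
    h_per_atp_m = h_per_atp_m,
    seed = as.integer(seed)
  ), class = "fixture_config")
}

# ---- species and reaction definitions ---------------------------------------

# carbon / nitrogen counts per molecule; cofactor counts are the true ones so
# that redox/adenylate pairs cancel exactly in the conservation check
fixture_species <- function() {
  def <- list(
    # id_base, name, carbon, nitrogen, compartments
    list("CO2", "carbon dioxide", 1, 0, c("c", "h", "m")),
    list("HCO3", "bicarbonate", 1, 0, "c"),
    list("O2", "oxygen", 0, 0, c("c", "h", "m", "p")),
    list("H2O", "water", 0, 0, c("c", "h", "m", "p")),
    list("H", "proton", 0, 0, c("c", "h", "m", "p")),
    list("H_lum", "thylakoid lumen proton", 0, 0, "h"),
    list("H_im", "intermembrane proton", 0, 0, "m"),
    list("Pi", "orthophosphate", 0, 0, c("c", "h", "m")),
    list("ATP", "ATP", 10, 5, c("c", "h", "m")),
    list("ADP", "ADP", 10, 5, c("c", "h", "m")),
    list("NADPH", "NADPH", 21, 7, c("c", "h", "m", "p")),
    list("NADP", "NADP+", 21, 7, c("c", "h", "m", "p")),
    list("NADH", "NADH", 21, 7, c("c", "m", "p")),
    list("NAD", "NAD+", 21, 7, c("c", "m", "p")),
    list("hnu", "photon", 0, 0, "h"),
    list("RuBP", "ribulose 1,5-bisphosphate", 5, 0, "h"),
    list("PGA", "3-phosphoglycerate", 3, 0, c("c", "h")),
    list("TP", "triose phosphate", 3, 0, c("c", "h")),
    list("PGyc", "2-phosphoglycolate", 2, 0, "h"),
    list("GCA", "glycolate", 2, 0, c("c", "h", "p")),
    list("GLX", "glyoxylate", 2, 0, "p"),
    list("GLY", "glycine", 2, 1, c("c", "m", "p")),
    list("SER", "serine", 3, 1, c("c", "m", "p")),
    list("HPR", "hydroxypyruvate", 3, 0, "p"),
    list("GCEA", "glycerate", 3, 0, c("c", "h", "p")),
    list("THF", "tetrahydrofolate", 19, 7, "m"),
    list("CH2THF", "5,10-methylene-THF", 20, 7, "m"),
    list("NH4", "ammonium", 0, 1, c("c", "h", "m")),
    list("NO3", "nitrate", 0, 1, "c"),
    list("NO2", "nitrite", 0, 1, c("c", "h")),
    list("GLN", "glutamine", 5, 2, "h"),
    list("GLU", "glutamate", 5, 1, c("c", "h", "m", "p")),
    list("AKG", "2-oxoglutarate", 5, 0, c("c", "h", "m", "p")),
    list("OAA", "oxaloacetate", 4, 0, c("c", "h", "m", "p")),
    list("MAL", "malate", 4, 0, c("c", "h", "m", "p")),
    list("PYR", "pyruvate", 3, 0, c("c", "h", "m")),
    list("PEP", "phosphoenolpyruvate", 3, 0, c("c", "h")),
    list("ASP", "aspartate", 4, 1, c("c", "h", "m")),
    list("ALA", "alanine", 3, 1, c("c", "h", "m")),
    list("ACA", "acetyl unit (acetyl-CoA)", 2, 0, "m"),
    list("CIT", "citrate", 6, 0, c("c", "m")),
    list("ICIT", "isocitrate", 6, 0, c("c", "h", "m")),
    list("HexP", "hexose phosphate", 6, 0, c("c", "h")),
    list("SUC", "sucrose", 12, 0, "c"),
    list("STARCH", "starch (12-carbon unit)", 12, 0, "h"),
    list("AA", "mean phloem amino acid", 5.5, 1, "c"),
    list("SO4", "sulfate", 0, 0, "c"),
    list("H2S", "hydrogen sulfide", 0, 0, "c")
  )
  bind_rows(map(def, function(d) {
    tibble(id = paste0(d[[1]], "_", d[[5]]), name = d[[2]],
           compartment = d[[5]], carbon = d[[3]], nitrogen = d[[4]])
  }))
}

# Reaction catalogue. `curation` marks reactions that the curation action set
# adds to the pre-curation core; `uncurated` carries the pre-curation variant
# (stoichiometry and/or bounds) for reactions the curation set modifies.
fixture_reactions <- function(cfg = fixture_config()) {
  INF <- INF_PROXY
  hA <- cfg$h_per_atp_h
  mA <- cfg$h_per_atp_m
  r <- function(id, stoich, lower = 0, upper = INF, subsystem, name = id,
                curation = FALSE, uncurated = NULL) {
    list(id = id, stoich = stoich, lower = lower, upper = upper,
         subsystem = subsystem, name = name, curation = curation,
         uncurated = uncurated)
  }
  rev <- function(id, stoich, subsystem, name = id, curation = FALSE,
                  uncurated = NULL) {
    r(id, stoich, -INF, INF, subsystem, name, curation, uncurated)
  }
  tr <- function(met, from) {
    # reversible uniport between compartment `from` and the cytosol
    rev(paste0("Tr_", met, "_", from, "c"),
        setNames(c(-1, 1), paste0(met, c(paste0("_", from), "_c"))),
        "intracellular transport",
        name = paste0(met, " transporter (", from, "/c)"))
  }
  tr_cur <- function(met, from) {
    x <- tr(met, from); x$curation <- TRUE; x
  }

  list(
    # -- light reactions (chloroplast) --
    # 8 photons move 4 electrons: 2 NADPH plus 8 lumen protons, an
    # ATP:NADPH yield of 4/3 — below the Calvin-cycle demand of 3/2, so
    # cyclic electron flow must top up ATP, as in the real thylakoid
    r("LEF_h", c(hnu_h = -8, H2O_h = -2, NADP_h = -2, H_h = -6,
                 NADPH_h = 2, O2_h = 1, H_lum_h = 8),
      subsystem = "light reactions", name = "linear electron flow (lumped)"),
    r("CEF_h", c(hnu_h = -2, H_h = -4, H_lum_h = 4),
      subsystem = "light reactions", name = "cyclic electron flow (lumped)",
      curation = TRUE),
    r("ATPSyn_h", c(ADP_h = -1, Pi_h = -1, H_lum_h = -hA,
                    ATP_h = 1, H2O_h = 1, H_h = hA),
      subsystem = "light reactions", name = "chloroplast ATP synthase",
      uncurated = list(stoich = c(ADP_h = -1, Pi_h = -1, H_lum_h = -14 / 3,
                                  ATP_h = 1, H2O_h = 1, H_h = 14 / 3))),
    r("AOX4_h", c(NADPH_h = -1, O2_h = -0.5, NADP_h = 1, H2O_h = 1),
      subsystem = "alternative respiration", name = "plastoquinol oxidase (lumped)",
      curation = TRUE),
    r("iCitDHNADP_h", c(ICIT_h = -1, NADP_h = -1, AKG_h = 1, CO2_h = 1,
                        NADPH_h = 1),
      subsystem = "TCA cycle", name = "chloroplastic NADP-isocitrate dehydrogenase"),

    # -- Calvin cycle (chloroplast) --
    r("RBC_h", c(RuBP_h = -1, CO2_h = -1, PGA_h = 2),
      subsystem = "Calvin cycle", name = "Rubisco carboxylase"),
    r("RBO_h", c(RuBP_h = -1, O2_h = -1, PGA_h = 1, PGyc_h = 1),
      subsystem = "photorespiration", name = "Rubisco oxygenase"),
    r("PGAred_h", c(PGA_h = -1, ATP_h = -1, NADPH_h = -1,
                    TP_h = 1, ADP_h = 1, NADP_h = 1, Pi_h = 1),
      subsystem = "Calvin cycle", name = "3-PGA reduction (lumped)"),
    r("RuBPreg_h", c(TP_h = -5, ATP_h = -3, RuBP_h = 3, ADP_h = 3, Pi_h = 2),
      subsystem = "Calvin cycle", name = "RuBP regeneration (lumped)"),
    r("FBPase_h", c(TP_h = -2, HexP_h = 1, Pi_h = 1),
      subsystem = "starch synthesis", name = "plastidic FBP aldolase/FBPase (lumped)"),
    r("StarchSyn_h", c(HexP_h = -2, ATP_h = -2, STARCH_h = 1, ADP_h = 2, Pi_h = 4),
      subsystem = "starch synthesis", name = "starch synthesis (12-C unit)"),

    # -- photorespiratory salvage --
    r("PGP_h", c(PGyc_h = -1, GCA_h = 1, Pi_h = 1),
      subsystem = "photorespiration", name = "phosphoglycolate phosphatase"),
    r("GOX_p", c(GCA_p = -1, O2_p = -0.5, GLX_p = 1, H2O_p = 1),
      subsystem = "photorespiration", name = "glycolate oxidase + catalase"),
    r("GGT_p", c(GLX_p = -1, GLU_p = -1, GLY_p = 1, AKG_p = 1),
      subsystem = "photorespiration", name = "glutamate:glyoxylate aminotransferase"),
    r("SGAT_p", c(GLX_p = -1, SER_p = -1, GLY_p = 1, HPR_p = 1),
      subsystem = "photorespiration", name = "serine:glyoxylate aminotransferase"),
    r("GDC_m", c(GLY_m = -1, THF_m = -1, NAD_m = -1,
                 CO2_m = 1, NH4_m = 1, CH2THF_m = 1, NADH_m = 1),
      subsystem = "photorespiration", name = "glycine decarboxylase complex",
      uncurated = list(lower = -INF)),
    r("SHMT_m", c(CH2THF_m = -1, GLY_m = -1, H2O_m = -1, SER_m = 1, THF_m = 1),
      subsystem = "photorespiration", name = "serine hydroxymethyltransferase"),
    r("HPRred_p", c(HPR_p = -1, NADH_p = -1, GCEA_p = 1, NAD_p = 1),
      subsystem = "photorespiration", name = "hydroxypyruvate reductase"),
    r("GLYK_h", c(GCEA_h = -1, ATP_h = -1, PGA_h = 1, ADP_h = 1),
      subsystem = "photorespiration", name = "glycerate kinase"),

    # -- nitrogen assimilation --
    r("NR_c", c(NO3_c = -1, NADH_c = -1, NO2_c = 1, NAD_c = 1),
      subsystem = "nitrate assimilation", name = "nitrate reductase"),
    r("NiR_h", c(NO2_h = -1, NADPH_h = -3, NH4_h = 1, NADP_h = 3),
      subsystem = "nitrate assimilation", name = "nitrite reductase (lumped)"),
    r("GS_h", c(NH4_h = -1, GLU_h = -1, ATP_h = -1, GLN_h = 1, ADP_h = 1, Pi_h = 1),
      subsystem = "glutamate biosynthesis", name = "glutamine synthetase"),
    r("GOGAT_h", c(GLN_h = -1, AKG_h = -1, NADPH_h = -1, GLU_h = 2, NADP_h = 1),
      subsystem = "glutamate biosynthesis", name = "glutamate synthase"),

    # -- C4 enzyme set --
    rev("CA_c", c(CO2_c = -1, H2O_c = -1, HCO3_c = 1, H_c = 1),
        subsystem = "C4 cycle", name = "carbonic anhydrase"),
    r("PEPC_c", c(PEP_c = -1, HCO3_c = -1, OAA_c = 1, Pi_c = 1),
      subsystem = "C4 cycle", name = "PEP carboxylase"),
    r("PPDK_h", c(PYR_h = -1, ATP_h = -2, PEP_h = 1, ADP_h = 2, Pi_h = 1),
      subsystem = "C4 cycle", name = "pyruvate phosphate dikinase (lumped)"),
    r("NADPME_h", c(MAL_h = -1, NADP_h = -1, PYR_h = 1, CO2_h = 1, NADPH_h = 1),
      subsystem = "C4 cycle", name = "NADP-malic enzyme",
      uncurated = list(lower = -INF)),
    r("NADME_m", c(MAL_m = -1, NAD_m = -1, PYR_m = 1, CO2_m = 1, NADH_m = 1),
      subsystem = "C4 cycle", name = "NAD-malic enzyme",
      uncurated = list(lower = -INF)),
    r("PEPCK_c", c(OAA_c = -1, ATP_c = -1, PEP_c = 1, CO2_c = 1, ADP_c = 1),
      subsystem = "C4 cycle", name = "PEP carboxykinase",
      uncurated = list(lower = -INF)),
    rev("NADPMDH_h", c(OAA_h = -1, NADPH_h = -1, H_h = -1, MAL_h = 1, NADP_h = 1),
        subsystem = "C4 cycle", name = "chloroplast NADP-malate dehydrogenase"),
    rev("MDH_c", c(OAA_c = -1, NADH_c = -1, MAL_c = 1, NAD_c = 1),
        subsystem = "malate shuttle", name = "cytosolic NAD-malate dehydrogenase",
        uncurated = list(stoich = c(OAA_c = -1, NADPH_c = -1, MAL_c = 1, NADP_c = 1))),
    rev("MDH_m", c(OAA_m = -1, NADH_m = -1, MAL_m = 1, NAD_m = 1),
        subsystem = "malate shuttle", name = "mitochondrial NAD-malate dehydrogenase",
        uncurated = list(stoich = c(OAA_m = -1, NADPH_m = -1, MAL_m = 1, NADP_m = 1))),
    rev("MDH_p", c(OAA_p = -1, NADH_p = -1, MAL_p = 1, NAD_p = 1),
        subsystem = "malate shuttle", name = "peroxisomal NAD-malate dehydrogenase",
        uncurated = list(stoich = c(OAA_p = -1, NADPH_p = -1, MAL_p = 1, NADP_p = 1))),
    rev("AspAT_c", c(OAA_c = -1, GLU_c = -1, ASP_c = 1, AKG_c = 1),
        subsystem = "C4 cycle", name = "aspartate aminotransferase (c)"),
    rev("AspAT_h", c(OAA_h = -1, GLU_h = -1, ASP_h = 1, AKG_h = 1),
        subsystem = "C4 cycle", name = "aspartate aminotransferase (h)"),
    rev("AspAT_m", c(OAA_m = -1, GLU_m = -1, ASP_m = 1, AKG_m = 1),
        subsystem = "C4 cycle", name = "aspartate aminotransferase (m)"),
    rev("AlaAT_c", c(PYR_c = -1, GLU_c = -1, ALA_c = 1, AKG_c = 1),
        subsystem = "C4 cycle", name = "alanine aminotransferase (c)",
        curation = TRUE),
    rev("AlaAT_h", c(PYR_h = -1, GLU_h = -1, ALA_h = 1, AKG_h = 1),
        subsystem = "C4 cycle", name = "alanine aminotransferase (h)",
        curation = TRUE),
    rev("AlaAT_m", c(PYR_m = -1, GLU_m = -1, ALA_m = 1, AKG_m = 1),
        subsystem = "C4 cycle", name = "alanine aminotransferase (m)",
        curation = TRUE),

    # -- glycolysis / gluconeogenesis (cytosol) --
    r("GAPDH_c", c(TP_c = -1, NAD_c = -1, ADP_c = -1, Pi_c = -1,
                   PGA_c = 1, NADH_c = 1, ATP_c = 1),
      subsystem = "canonical glycolysis", name = "lower glycolysis to 3-PGA (lumped)"),
    rev("ENO_c", c(PGA_c = -1, PEP_c = 1, H2O_c = 1),
        subsystem = "canonical glycolysis", name = "phosphoglycerate mutase/enolase"),
    r("PK_c", c(PEP_c = -1, ADP_c = -1, PYR_c = 1, ATP_c = 1),
      subsystem = "canonical glycolysis", name = "pyruvate kinase"),
    r("FBPase_c", c(TP_c = -2, HexP_c = 1, Pi_c = 1),
      subsystem = "sucrose synthesis", name = "cytosolic FBP aldolase/FBPase (lumped)"),
    r("PFK_c", c(HexP_c = -1, ATP_c = -1, TP_c = 2, ADP_c = 1),
      subsystem = "canonical glycolysis", name = "phosphofructokinase/aldolase (lumped)"),

    # -- TCA cycle and respiration (mitochondria) --
    r("PDH_m", c(PYR_m = -1, NAD_m = -1, ACA_m = 1, CO2_m = 1, NADH_m = 1),
      subsystem = "pyruvate dehydrogenase", name = "pyruvate dehydrogenase",
      uncurated = list(lower = -INF)),
    r("CS_m", c(ACA_m = -1, OAA_m = -1, H2O_m = -1, CIT_m = 1),
      subsystem = "TCA cycle", name = "citrate synthase"),
    rev("ACO_m", c(CIT_m = -1, ICIT_m = 1),
        subsystem = "TCA cycle", name = "aconitase (m)"),
    rev("ACO_c", c(CIT_c = -1, ICIT_c = 1),
        subsystem = "TCA cycle", name = "aconitase (c)"),
    r("IDH_m", c(ICIT_m = -1, NAD_m = -1, AKG_m = 1, CO2_m = 1, NADH_m = 1),
      subsystem = "TCA cycle", name = "NAD-isocitrate dehydrogenase",
      uncurated = list(lower = -INF)),
    r("AKGDH_m", c(AKG_m = -1, NAD_m = -3, ADP_m = -1, Pi_m = -1,
                   OAA_m = 1, CO2_m = 1, NADH_m = 3, ATP_m = 1),
      subsystem = "TCA cycle", name = "2-OG to OAA (lumped TCA arm)",
      uncurated = list(lower = -INF)),
    r("ETC_m", c(NADH_m = -1, O2_m = -0.5, H_m = -10,
                 NAD_m = 1, H2O_m = 1, H_im_m = 10),
      subsystem = "oxidative phosphorylation", name = "respiratory chain (lumped)"),
    r("ATPSyn_m", c(ADP_m = -1, Pi_m = -1, H_im_m = -mA,
                    ATP_m = 1, H2O_m = 1, H_m = mA),
      subsystem = "oxidative phosphorylation", name = "mitochondrial ATP synthase",
      uncurated = list(stoich = c(ADP_m = -1, Pi_m = -1, H_im_m = -3,
                                  ATP_m = 1, H2O_m = 1, H_m = 3))),
    r("AOX_m", c(NADH_m = -1, O2_m = -0.5, NAD_m = 1, H2O_m = 1),
      subsystem = "alternative respiration", name = "mitochondrial alternative oxidase",
      curation = TRUE),

    # -- output synthesis --
    r("SPS_c", c(HexP_c = -2, ATP_c = -1, SUC_c = 1, ADP_c = 1, Pi_c = 3),
      subsystem = "sucrose synthesis", name = "sucrose synthesis (lumped)"),
    r("AAsyn_c", c(GLU_c = -1, HexP_c = -1 / 12, ATP_c = -2,
                   AA_c = 1, ADP_c = 2, Pi_c = 2),
      subsystem = "amino acid synthesis",
      name = "mean phloem amino acid synthesis (lumped)"),

    # -- intracellular transport --
    tr("CO2", "h"), tr("CO2", "m"),
    tr("O2", "h"), tr("O2", "m"), tr("O2", "p"),
    tr("H2O", "h"), tr("H2O", "m"), tr("H2O", "p"),
    tr("Pi", "h"), tr("Pi", "m"),
    tr("TP", "h"), tr("PGA", "h"), tr("PEP", "h"),
    tr("GCA", "h"), tr("GCA", "p"),
    tr("GCEA", "h"), tr("GCEA", "p"),
    tr("GLY", "m"), tr("GLY", "p"),
    tr("SER", "m"), tr("SER", "p"),
    tr("GLU", "p"), tr("AKG", "p"),
    tr("MAL", "p"), tr("OAA", "p"),
    tr("NH4", "m"), tr("NH4", "h"),
    tr("NO2", "h"), tr("PYR", "m"),
    # transporters added during curation (DiT/DTC/AGC/BT/APC analogues)
    tr_cur("MAL", "h"), tr_cur("OAA", "h"), tr_cur("PYR", "h"),
    tr_cur("GLU", "h"), tr_cur("AKG", "h"), tr_cur("ICIT", "h"),
    tr_cur("MAL", "m"), tr_cur("OAA", "m"), tr_cur("CIT", "m"),
    tr_cur("ICIT", "m"), tr_cur("AKG", "m"), tr_cur("ASP", "m"),
    tr_cur("GLU", "m"), tr_cur("ALA", "m"),
    {
      x <- rev("Tr_ATP_mc", c(ATP_m = -1, ADP_c = -1, ATP_c = 1, ADP_m = 1),
               subsystem = "intracellular transport",
               name = "mitochondrial ATP/ADP carrier")
      x$curation <- TRUE; x
    },
    {
      x <- rev("Tr_ATP_hc", c(ATP_h = -1, ADP_c = -1, ATP_c = 1, ADP_h = 1),
               subsystem = "intracellular transport",
               name = "chloroplastic ATP/ADP carrier")
      x$curation <- TRUE; x
    },
    rev("Tr_ASP_hc", c(ASP_h = -1, ASP_c = 1),
        subsystem = "intracellular transport", name = "ASP transporter (h/c)"),
    rev("Tr_ALA_hc", c(ALA_h = -1, ALA_c = 1),
        subsystem = "intracellular transport", name = "ALA transporter (h/c)"),

    # -- boundary exchanges (bounds per the photoautotrophic table) --
    r("Im_hnu", c(hnu_h = 1), 0, INF, "exchange", "photon import"),
    r("Im_CO2", c(CO2_c = 1), 0, 20, "exchange", "CO2 import"),
    r("Im_NO3", c(NO3_c = 1), 0, INF, "exchange", "nitrate import"),
    r("Im_NH4", c(NH4_c = 1), 0, 0, "exchange", "ammonium import (closed)"),
    r("Im_SO4", c(SO4_c = 1), 0, INF, "exchange", "sulfate import"),
    r("Im_H2S", c(H2S_c = 1), 0, INF, "exchange", "hydrogen sulfide import"),
    r("Im_Pi", c(Pi_c = 1), 0, INF, "exchange", "phosphate import"),
    r("Im_H2O", c(H2O_c = 1), -INF, INF, "exchange", "water exchange"),
    r("Im_O2", c(O2_c = 1), -INF, INF, "exchange", "oxygen exchange"),
    r("Ex_Suc", c(SUC_c = -1), 0, INF, "exchange", "sucrose export"),
    r("Ex_AA", c(AA_c = -1), 0, INF, "exchange", "amino acid export"),
    r("Ex_starch", c(STARCH_h = -1), 0, INF, "exchange", "starch export"),
    r("Ex_CO2", c(CO2_c = -1), 0, 0, "exchange", "CO2 export (closed)")
  )
}

subsystem_groups <- function() {
  list(
    light_reactions = c("LEF_h", "ATPSyn_h"),
    cyclic_electron_flow = "CEF_h",
    calvin_cycle = c("RBC_h", "PGAred_h", "RuBPreg_h"),
    photorespiration = c("RBO_h", "PGP_h", "GOX_p", "GGT_p", "SGAT_p",
                         "GDC_m", "SHMT_m", "HPRred_p", "GLYK_h"),
    c4_enzymes = c("CA_c", "PEPC_c", "PPDK_h", "NADPME_h", "NADME_m",
                   "PEPCK_c", "NADPMDH_h", "AspAT_c", "AspAT_h", "AspAT_m",
                   "AlaAT_c", "AlaAT_h", "AlaAT_m"),
    tca_oxphos = c("PDH_m", "CS_m", "ACO_m", "ACO_c", "IDH_m", "AKGDH_m",
                   "ETC_m", "ATPSyn_m", "iCitDHNADP_h"),
    alternative_oxidase = c("AOX_m", "AOX4_h"),
    nitrate_assimilation = c("NR_c", "NiR_h", "GS_h", "GOGAT_h"),
    output_synthesis = c("FBPase_h", "StarchSyn_h", "FBPase_c", "SPS_c",
                         "AAsyn_c")
  )
}

#' Generate the reduced leaf metabolic network
#'
#' Deterministically builds a compartmented (c/h/m/p) leaf network of about
#' a hundred reactions that is exactly carbon- and nitrogen-balanced by
#' construction. With `curated = TRUE` (default) the network carries the
#' curated state: NAD-dependent malate dehydrogenases outside the
#' chloroplast, cyclic electron flow and alternative oxidases present,
#' H+/ATP stoichiometry 3:1 (chloroplast) and 4:1 (mitochondria),
#' decarboxylases unidirectional towards decarboxylation, and zero-flux caps
#' on the chloroplastic NADP-dehydrogenase, plastoquinol oxidase and ADP/ATP
#' carrier. With `curated = FALSE` it emits the pre-curation core on which
#' [apply_curation()] with [default_curation()] reproduces the curated state.
#'
#' @param config a [fixture_config()].
#' @param curated emit the curated (default) or pre-curation variant.
#' @return A `metabolic_model` (no proton buffers, maintenance reactions or
#'   flux-ratio constraints yet; see [compose_one_cell()]).
#' @export
build_reduced_leaf_network <- function(config = fixture_config(),
                                       curated = TRUE) {
  stopifnot(inherits(config, "fixture_config"))
  defs <- fixture_reactions(config)
  groups <- subsystem_groups()
  off <- names(config$include)[!config$include]
  drop_ids <- unique(unlist(groups[intersect(off, names(groups))]))
  if (!is.null(config$include["transporters"]) && !config$include[["transporters"]]) {
    drop_ids <- c(drop_ids, grep("^Tr_", map_chr(defs, "id"), value = TRUE))
  }

  mets <- fixture_species()
  model <- metabolic_model(metabolites = mets,
                           compartments = c("c", "h", "m", "p"))
  for (d in defs) {
    if (d$id %in% drop_ids) next
    if (!curated) {
      if (isTRUE(d$curation)) next
      if (!is.null(d$uncurated)) {
        if (!is.null(d$uncurated$stoich)) d$stoich <- d$uncurated$stoich
        if (!is.null(d$uncurated$lower)) d$lower <- d$uncurated$lower
        if (!is.null(d$uncurated$upper)) d$upper <- d$uncurated$upper
      }
    }
    model <- add_reaction(model, d$id, d$stoich, d$lower, d$upper,
                          name = d$name, subsystem = d$subsystem)
  }
  if (curated) {
    # zero-flux assumptions of the curated model
    for (id in intersect(c("iCitDHNADP_h", "AOX4_h", "Tr_ATP_hc"),
                         model$reactions$id)) {
      model <- set_bounds(model, id, lower = 0, upper = 0)
    }
  }
  model$annotations$generator <- "reduced_leaf_network"
  model$annotations$curated <- curated
  model$annotations$config_seed <- config$seed
  validate_model(model)
  model
}

#' Assemble the ready-to-solve one-cell model
#'
#' Pipeline over the generated (or any compatible) curated network: proton
#' buffers for every compartment, fixed maintenance fluxes, the
#' photoautotrophic boundary, the phloem export ratio constraints
#' (sucrose : amino acids = `suc_aa`, sucrose : starch = `suc_starch`), the
#' photorespiration ratio on the native Rubisco pair, and the phloem-output
#' objective.
#'
#' @param network a curated `metabolic_model`; defaults to the generated
#'   reduced leaf network.
#' @param photorespiration oxygenation : carboxylation ratio (ambient 0.1).
#' @param suc_aa sucrose : amino-acid export flux ratio.
#' @param suc_starch sucrose : starch export flux ratio.
#' @param maintenance per-compartment costs, see [default_maintenance()].
#' @param boundary a [boundary_spec()].
#' @return A solvable `metabolic_model` maximizing phloem output.
#' @export
compose_one_cell <- function(network = build_reduced_leaf_network(),
                             photorespiration = 0.1,
                             suc_aa = 2.2,
                             suc_starch = 1,
                             maintenance = default_maintenance(),
                             boundary = default_boundary_spec()) {
  network %>%
    add_proton_buffers() %>%
    add_maintenance(maintenance) %>%
    set_boundary(boundary) %>%
    add_ratio_constraint("Ex_Suc", "Ex_AA", suc_aa, id = "export:suc_aa") %>%
    add_ratio_constraint("Ex_Suc", "Ex_starch", suc_starch,
                         id = "export:suc_starch") %>%
    fix_photorespiration(photorespiration, "RBO_h", "RBC_h") %>%
    set_objective(c(Ex_Suc = 1, Ex_AA = 1), "max")
}

#' Multiplicatively jitter the non-fixed bounds of a model
#'
#' Property-testing support: every bound of a reaction whose bounds are not
#' an equality pair is scaled by an independent factor in
#' `[1 - jitter_fraction, 1 + jitter_fraction]`, deterministically in `seed`.
#' Equality (fixed-flux) bounds are skipped and reported in the
#' `"skipped_fixed"` attribute.
#'
#' @param model a `metabolic_model`.
#' @param seed integer seed.
#' @param jitter_fraction maximal relative perturbation, in `[0, 1)`.
#' @return The perturbed model.
#' @export
perturb_fixture <- function(model, seed, jitter_fraction = 0.1) {
  stopifnot(jitter_fraction >= 0, jitter_fraction < 1)
  free <- which(model$reactions$lower < model$reactions$upper)
  fixed <- model$reactions$id[model$reactions$lower == model$reactions$upper]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  u <- matrix(stats::runif(2 * length(free), -jitter_fraction, jitter_fraction),
              ncol = 2)
  lo <- model$reactions$lower[free] * (1 + u[, 1])
  up <- model$reactions$upper[free] * (1 + u[, 2])
  swap <- lo > up
  if (any(swap)) {
    mid <- (lo[swap] + up[swap]) / 2
    lo[swap] <- mid; up[swap] <- mid
  }
  model$reactions$lower[free] <- lo
  model$reactions$upper[free] <- up
  validate_model(model)
  attr(model, "skipped_fixed") <- fixed
  model
}

# Guard used by experiment drivers: fail with the missing dependency named.
require_reactions <- function(model, ids, context) {
  missing <- setdiff(ids, model$reactions$id)
  if (length(missing) > 0) {
    abort(paste0(context, " requires reaction(s) absent from the model: ",
                 paste(missing, collapse = ", "),
                 " (was the subsystem excluded from the fixture config?)"))
  }
  invisible(TRUE)
}
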