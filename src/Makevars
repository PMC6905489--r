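# libglpk ships with the same conda prefix that provides R itself
CONDA_PREFIX_FROM_R = $(R_HOME)/../..
PKG_CPPFLAGS = -I$(CONDA_PREFIX_FROM_R)/include
PKG_LIBS = -L$(CONDA_PREFIX_FROM_R)/lib -lglpk -Wl,-rpath,$(CONDA_PREFIX_FROM_R)/lib
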