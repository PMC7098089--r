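# The toolchain's default -march=nocona (2004 ISA baseline) cripples the
# hand-written compute loops; append flags for the machine the package is
# installed on. `override` is needed because the defaults arrive via make
# command-line variables.
override CXXFLAGS += -O3 -march=native -funroll-loops
override CXX17FLAGS += -O3 -march=native -funroll-loops
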