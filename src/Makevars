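# The fused convolution kernels are compute-bound elementwise loops with
# dot-product reductions; build for the host ISA (the package is always
# compiled on the machine it runs on) at -O3 and allow reassociation so the
# reductions vectorize. -fno-finite-math-only is NOT implied here: the
# flags below keep isfinite() meaningful.
PKG_CXXFLAGS = -O3 -march=native -funroll-loops -fno-math-errno \
	-funsafe-math-optimizations -fno-trapping-math
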