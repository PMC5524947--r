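PKG_CPPFLAGS = -DARMA_USE_CURRENT -DARMA_USE_FFTW3
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS) -lfftw3
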