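PKG_LIBS = -lhdf5 -llz4 -lzstd -lz
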