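#ifndef JFPROC_H
#define JFPROC_H

#include <R.h>
#include <Rinternals.h>
#include <stdint.h>
#include <string.h>

/* bitshuffle.c */
void jf_bitshuffle_core(const unsigned char *in, unsigned char *out,
                        size_t n_elem, int elem_size, int order);
void jf_bitunshuffle_core(const unsigned char *in, unsigned char *out,
                          size_t n_elem, int elem_size, int order);
SEXP C_bitshuffle(SEXP bytes, SEXP elem_size, SEXP order);
SEXP C_bitunshuffle(SEXP bytes, SEXP elem_size, SEXP order);
SEXP C_pack_u16(SEXP x);
SEXP C_unpack_u16(SEXP bytes);

/* codecs.c */
SEXP C_lz4_compress(SEXP bytes);
SEXP C_lz4_decompress(SEXP bytes, SEXP n_out);
SEXP C_zstd_compress(SEXP bytes, SEXP level);
SEXP C_zstd_decompress(SEXP bytes);
SEXP C_zlib_compress(SEXP bytes, SEXP level);
SEXP C_zlib_decompress(SEXP bytes, SEXP n_out);
SEXP C_bshuf_compress(SEXP bytes, SEXP elem_size, SEXP block_bytes,
                      SEXP codec, SEXP shuffle, SEXP level);
SEXP C_bshuf_decompress(SEXP bytes, SEXP args);
int64_t jf_bshuf_compress_buf(const unsigned char *in, size_t n,
                              unsigned char *out, size_t out_cap,
                              int elem_size, size_t block_bytes,
                              int codec, int shuffle, int level);
int64_t jf_bshuf_decompress_buf(const unsigned char *in, size_t n_in,
                                unsigned char *out, size_t out_cap,
                                int elem_size, int shuffle, int codec);
size_t jf_bshuf_bound(size_t n, size_t block_bytes);

/* lossy.c */
SEXP C_lossy_encode(SEXP x, SEXP nrow, SEXP ncol, SEXP e);
SEXP C_lossy_decode(SEXP codes, SEXP escapes, SEXP nrow, SEXP ncol, SEXP e);

/* hdf5io.c */
SEXP C_h5_write_map_file(SEXP path, SEXP group, SEXP names, SEXP maps);
SEXP C_h5_read_map_file(SEXP path, SEXP group);
SEXP C_h5_write_stack(SEXP path, SEXP chunks, SEXP dims, SEXP dtype,
                      SEXP images_per_dataset, SEXP filter_info, SEXP attrs);
SEXP C_h5_read_stack(SEXP path);
SEXP C_h5_read_dataset_filtered(SEXP path, SEXP dset);
SEXP C_h5_register_filters(void);

#endif
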