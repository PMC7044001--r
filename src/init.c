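#include "jfproc.h"
#include <R_ext/Rdynload.h>

static const R_CallMethodDef call_entries[] = {
    {"C_bitshuffle", (DL_FUNC)&C_bitshuffle, 3},
    {"C_bitunshuffle", (DL_FUNC)&C_bitunshuffle, 3},
    {"C_pack_u16", (DL_FUNC)&C_pack_u16, 1},
    {"C_unpack_u16", (DL_FUNC)&C_unpack_u16, 1},
    {"C_lz4_compress", (DL_FUNC)&C_lz4_compress, 1},
    {"C_lz4_decompress", (DL_FUNC)&C_lz4_decompress, 2},
    {"C_zstd_compress", (DL_FUNC)&C_zstd_compress, 2},
    {"C_zstd_decompress", (DL_FUNC)&C_zstd_decompress, 1},
    {"C_zlib_compress", (DL_FUNC)&C_zlib_compress, 2},
    {"C_zlib_decompress", (DL_FUNC)&C_zlib_decompress, 2},
    {"C_bshuf_compress", (DL_FUNC)&C_bshuf_compress, 6},
    {"C_bshuf_decompress", (DL_FUNC)&C_bshuf_decompress, 2},
    {"C_lossy_encode", (DL_FUNC)&C_lossy_encode, 4},
    {"C_lossy_decode", (DL_FUNC)&C_lossy_decode, 5},
    {"C_h5_write_map_file", (DL_FUNC)&C_h5_write_map_file, 4},
    {"C_h5_read_map_file", (DL_FUNC)&C_h5_read_map_file, 2},
    {"C_h5_write_stack", (DL_FUNC)&C_h5_write_stack, 7},
    {"C_h5_read_stack", (DL_FUNC)&C_h5_read_stack, 1},
    {"C_h5_read_dataset_filtered", (DL_FUNC)&C_h5_read_dataset_filtered, 2},
    {"C_h5_register_filters", (DL_FUNC)&C_h5_register_filters, 0},
    {NULL, NULL, 0}
};

void R_init_jfproc(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
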