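/* Bit-plane transposition (Bitshuffle) for 16- and 32-bit elements.
 *
 * Two plane orderings are supported:
 *   order 0 ("msb"):    planes run from the most significant bit of the
 *                       element value down to the least significant bit.
 *   order 1 ("filter"): planes are grouped by memory byte (little-endian,
 *                       least significant byte first) and run MSB-first
 *                       within each byte -- the layout produced by the
 *                       unpackbits/transpose/packbits construction used by
 *                       the HDF5 bitshuffle filter.
 * Within a plane, element 0 lands in the most significant bit of its byte.
 */
#include "jfproc.h"

static void plane_coords(int p, int elem_size, int order, int *byte_idx, int *bit_idx)
{
    if (order == 0) {
        int q = elem_size * 8 - 1 - p;  /* value bit index, little-endian bytes */
        *byte_idx = q / 8;
        *bit_idx = q % 8;
    } else {
        *byte_idx = p / 8;
        *bit_idx = 7 - (p % 8);
    }
}

void jf_bitshuffle_core(const unsigned char *in, unsigned char *out,
                        size_t n_elem, int elem_size, int order)
{
    size_t nb = n_elem / 8; /* bytes per plane */
    int n_planes = elem_size * 8;
    for (int p = 0; p < n_planes; p++) {
        int byte_idx, bit_idx;
        plane_coords(p, elem_size, order, &byte_idx, &bit_idx);
        unsigned char *dst = out + (size_t)p * nb;
        for (size_t j = 0; j < nb; j++) {
            const unsigned char *src = in + (size_t)(j * 8) * elem_size + byte_idx;
            unsigned char b = 0;
            for (int k = 0; k < 8; k++)
                b |= (unsigned char)(((src[(size_t)k * elem_size] >> bit_idx) & 1u) << (7 - k));
            dst[j] = b;
        }
    }
}

void jf_bitunshuffle_core(const unsigned char *in, unsigned char *out,
                          size_t n_elem, int elem_size, int order)
{
    size_t nb = n_elem / 8;
    int n_planes = elem_size * 8;
    memset(out, 0, n_elem * (size_t)elem_size);
    for (int p = 0; p < n_planes; p++) {
        int byte_idx, bit_idx;
        plane_coords(p, elem_size, order, &byte_idx, &bit_idx);
        const unsigned char *src = in + (size_t)p * nb;
        for (size_t j = 0; j < nb; j++) {
            unsigned char b = src[j];
            unsigned char *dst = out + (size_t)(j * 8) * elem_size + byte_idx;
            for (int k = 0; k < 8; k++)
                dst[(size_t)k * elem_size] |=
                    (unsigned char)(((b >> (7 - k)) & 1u) << bit_idx);
        }
    }
}

static void check_args(SEXP bytes, int elem, int order, size_t *n_elem)
{
    if (elem != 2 && elem != 4)
        Rf_error("element size must be 2 or 4 bytes");
    if (order != 0 && order != 1)
        Rf_error("unknown plane order");
    size_t n = (size_t)XLENGTH(bytes);
    if (n % (size_t)elem != 0)
        Rf_error("byte count %lld is not a multiple of the element size",
                 (long long)n);
    *n_elem = n / (size_t)elem;
    if (*n_elem % 8 != 0)
        Rf_error("element count %lld is not a multiple of 8",
                 (long long)*n_elem);
}

SEXP C_bitshuffle(SEXP bytes, SEXP elem_size, SEXP order)
{
    int elem = Rf_asInteger(elem_size), ord = Rf_asInteger(order);
    size_t n_elem;
    check_args(bytes, elem, ord, &n_elem);
    SEXP out = PROTECT(Rf_allocVector(RAWSXP, XLENGTH(bytes)));
    jf_bitshuffle_core(RAW(bytes), RAW(out), n_elem, elem, ord);
    UNPROTECT(1);
    return out;
}

SEXP C_bitunshuffle(SEXP bytes, SEXP elem_size, SEXP order)
{
    int elem = Rf_asInteger(elem_size), ord = Rf_asInteger(order);
    size_t n_elem;
    check_args(bytes, elem, ord, &n_elem);
    SEXP out = PROTECT(Rf_allocVector(RAWSXP, XLENGTH(bytes)));
    jf_bitunshuffle_core(RAW(bytes), RAW(out), n_elem, elem, ord);
    UNPROTECT(1);
    return out;
}

/* Little-endian 16-bit packing for raw pixel words stored in R integers. */
SEXP C_pack_u16(SEXP x)
{
    R_xlen_t n = XLENGTH(x);
    const int *xi = INTEGER(x);
    SEXP out = PROTECT(Rf_allocVector(RAWSXP, 2 * n));
    unsigned char *o = RAW(out);
    for (R_xlen_t i = 0; i < n; i++) {
        int v = xi[i];
        if (v == NA_INTEGER || v < 0 || v > 0xFFFF)
            Rf_error("value out of 16-bit range at position %lld",
                     (long long)(i + 1));
        o[2 * i] = (unsigned char)(v & 0xFF);
        o[2 * i + 1] = (unsigned char)((v >> 8) & 0xFF);
    }
    UNPROTECT(1);
    return out;
}

SEXP C_unpack_u16(SEXP bytes)
{
    R_xlen_t n = XLENGTH(bytes);
    if (n % 2 != 0)
        Rf_error("byte count is not a multiple of 2");
    const unsigned char *b = RAW(bytes);
    SEXP out = PROTECT(Rf_allocVector(INTSXP, n / 2));
    int *o = INTEGER(out);
    for (R_xlen_t i = 0; i < n / 2; i++)
        o[i] = (int)b[2 * i] | ((int)b[2 * i + 1] << 8);
    UNPROTECT(1);
    return out;
}
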