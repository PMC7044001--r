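/* Eiger-dialect HDF5 output with pre-compressed direct chunk writing.
 *
 * Layout: /entry/data/data_%06d, one frame per chunk (1 x H x W), with
 * image_nr_low/image_nr_high attributes per dataset and a provenance
 * attribute block under /entry/jfproc.  Compression happens upstream (the
 * compression module); chunks are handed to the HDF5 library already
 * compressed via H5Dwrite_chunk, as the library's own filter pipeline is
 * not thread safe.  Filters 32008 (bitshuffle+codec), 32004 (LZ4) and
 * 32015 (Zstd) are registered with decode callbacks so files can also be
 * read through the regular H5Dread path.
 */
#include "jfproc.h"
#include <hdf5.h>
#include <zlib.h>
#include <zstd.h>

#define JF_FILTER_BSHUF 32008
#define JF_FILTER_LZ4 32004
#define JF_FILTER_ZSTD 32015

static uint64_t rd_be64(const unsigned char *p)
{
    uint64_t v = 0;
    for (int i = 0; i < 8; i++) v = (v << 8) | p[i];
    return v;
}

/* ---- filter callbacks ---------------------------------------------------- */

static size_t filter_bshuf(unsigned flags, size_t cd_nelmts,
                           const unsigned cd_values[], size_t nbytes,
                           size_t *buf_size, void **buf)
{
    int elem = cd_nelmts > 2 ? (int)cd_values[2] : 4;
    size_t block_elems = cd_nelmts > 3 ? cd_values[3] : 0;
    int codec = cd_nelmts > 4 ? (int)cd_values[4] : 2;
    if (flags & H5Z_FLAG_REVERSE) {
        uint64_t n = rd_be64((const unsigned char *)*buf);
        void *out = H5allocate_memory((size_t)n, 0);
        if (!out) return 0;
        jf_bshuf_decompress_buf((const unsigned char *)*buf, nbytes,
                                (unsigned char *)out, (size_t)n, elem, 1, codec);
        H5free_memory(*buf);
        *buf = out;
        *buf_size = (size_t)n;
        return (size_t)n;
    }
    size_t block_bytes = block_elems ? block_elems * (size_t)elem : 8192;
    size_t cap = jf_bshuf_bound(nbytes, block_bytes);
    void *out = H5allocate_memory(cap, 0);
    if (!out) return 0;
    int64_t sz = jf_bshuf_compress_buf((const unsigned char *)*buf, nbytes,
                                       (unsigned char *)out, cap, elem,
                                       block_bytes, codec, 1, 3);
    H5free_memory(*buf);
    *buf = out;
    *buf_size = cap;
    return (size_t)sz;
}

static size_t filter_lz4(unsigned flags, size_t cd_nelmts,
                         const unsigned cd_values[], size_t nbytes,
                         size_t *buf_size, void **buf)
{
    int elem = cd_nelmts > 1 ? (int)cd_values[1] : 2;
    if (flags & H5Z_FLAG_REVERSE) {
        uint64_t n = rd_be64((const unsigned char *)*buf);
        void *out = H5allocate_memory((size_t)n, 0);
        if (!out) return 0;
        jf_bshuf_decompress_buf((const unsigned char *)*buf, nbytes,
                                (unsigned char *)out, (size_t)n, elem, 0, 2);
        H5free_memory(*buf);
        *buf = out;
        *buf_size = (size_t)n;
        return (size_t)n;
    }
    size_t block_bytes = cd_nelmts > 0 && cd_values[0] ? cd_values[0] : 8192;
    size_t cap = jf_bshuf_bound(nbytes, block_bytes);
    void *out = H5allocate_memory(cap, 0);
    if (!out) return 0;
    int64_t sz = jf_bshuf_compress_buf((const unsigned char *)*buf, nbytes,
                                       (unsigned char *)out, cap, elem,
                                       block_bytes, 2, 0, 3);
    H5free_memory(*buf);
    *buf = out;
    *buf_size = cap;
    return (size_t)sz;
}

static size_t filter_zstd(unsigned flags, size_t cd_nelmts,
                          const unsigned cd_values[], size_t nbytes,
                          size_t *buf_size, void **buf)
{
    if (flags & H5Z_FLAG_REVERSE) {
        unsigned long long n = ZSTD_getFrameContentSize(*buf, nbytes);
        if (n == ZSTD_CONTENTSIZE_ERROR || n == ZSTD_CONTENTSIZE_UNKNOWN)
            return 0;
        void *out = H5allocate_memory((size_t)n, 0);
        if (!out) return 0;
        size_t sz = ZSTD_decompress(out, (size_t)n, *buf, nbytes);
        if (ZSTD_isError(sz)) { H5free_memory(out); return 0; }
        H5free_memory(*buf);
        *buf = out;
        *buf_size = (size_t)n;
        return (size_t)n;
    }
    int level = cd_nelmts > 0 ? (int)cd_values[0] : 3;
    size_t cap = ZSTD_compressBound(nbytes);
    void *out = H5allocate_memory(cap, 0);
    if (!out) return 0;
    size_t sz = ZSTD_compress(out, cap, *buf, nbytes, level);
    if (ZSTD_isError(sz)) { H5free_memory(out); return 0; }
    H5free_memory(*buf);
    *buf = out;
    *buf_size = cap;
    return sz;
}

SEXP C_h5_register_filters(void)
{
    H5Eset_auto2(H5E_DEFAULT, NULL, NULL);
    H5Z_class2_t cls;
    memset(&cls, 0, sizeof(cls));
    cls.version = H5Z_CLASS_T_VERS;
    cls.encoder_present = 1;
    cls.decoder_present = 1;

    if (!H5Zfilter_avail(JF_FILTER_BSHUF)) {
        cls.id = JF_FILTER_BSHUF;
        cls.name = "bitshuffle; see https://github.com/kiyo-masui/bitshuffle";
        cls.filter = filter_bshuf;
        H5Zregister(&cls);
    }
    if (!H5Zfilter_avail(JF_FILTER_LZ4)) {
        cls.id = JF_FILTER_LZ4;
        cls.name = "HDF5 lz4 filter";
        cls.filter = filter_lz4;
        H5Zregister(&cls);
    }
    if (!H5Zfilter_avail(JF_FILTER_ZSTD)) {
        cls.id = JF_FILTER_ZSTD;
        cls.name = "Zstandard compression filter";
        cls.filter = filter_zstd;
        H5Zregister(&cls);
    }
    return R_NilValue;
}

/* ---- helpers ------------------------------------------------------------- */

static void chk(hid_t v, const char *what)
{
    if (v < 0) Rf_error("HDF5 error in %s", what);
}

/* reproducible files: no object modification timestamps */
static hid_t notime_plist(hid_t cls)
{
    hid_t p = H5Pcreate(cls);
    H5Pset_obj_track_times(p, 0);
    return p;
}

static void attr_string(hid_t loc, const char *name, const char *value)
{
    hid_t sp = H5Screate(H5S_SCALAR);
    hid_t ty = H5Tcopy(H5T_C_S1);
    H5Tset_size(ty, strlen(value) + 1);
    H5Tset_strpad(ty, H5T_STR_NULLTERM);
    hid_t at = H5Acreate2(loc, name, ty, sp, H5P_DEFAULT, H5P_DEFAULT);
    chk(at, "attribute creation");
    H5Awrite(at, ty, value);
    H5Aclose(at); H5Tclose(ty); H5Sclose(sp);
}

static void attr_double(hid_t loc, const char *name, double value)
{
    hid_t sp = H5Screate(H5S_SCALAR);
    hid_t at = H5Acreate2(loc, name, H5T_IEEE_F64LE, sp, H5P_DEFAULT, H5P_DEFAULT);
    chk(at, "attribute creation");
    H5Awrite(at, H5T_NATIVE_DOUBLE, &value);
    H5Aclose(at); H5Sclose(sp);
}

static void attr_int(hid_t loc, const char *name, int value)
{
    hid_t sp = H5Screate(H5S_SCALAR);
    hid_t at = H5Acreate2(loc, name, H5T_STD_I32LE, sp, H5P_DEFAULT, H5P_DEFAULT);
    chk(at, "attribute creation");
    H5Awrite(at, H5T_NATIVE_INT, &value);
    H5Aclose(at); H5Sclose(sp);
}

/* ---- per-pixel map container (calibration files) ------------------------- */

SEXP C_h5_write_map_file(SEXP path, SEXP group, SEXP names, SEXP maps)
{
    const char *p = CHAR(STRING_ELT(path, 0));
    hid_t fcpl = notime_plist(H5P_FILE_CREATE);
    hid_t file = H5Fcreate(p, H5F_ACC_TRUNC, fcpl, H5P_DEFAULT);
    H5Pclose(fcpl);
    chk(file, "file creation");
    hid_t gcpl = notime_plist(H5P_GROUP_CREATE);
    hid_t grp = H5Gcreate2(file, CHAR(STRING_ELT(group, 0)), H5P_DEFAULT,
                           gcpl, H5P_DEFAULT);
    chk(grp, "group creation");
    int nmap = (int)XLENGTH(maps);
    for (int i = 0; i < nmap; i++) {
        SEXP m = VECTOR_ELT(maps, i);
        SEXP dm = Rf_getAttrib(m, R_DimSymbol);
        int nr = INTEGER(dm)[0], nc = INTEGER(dm)[1];
        hsize_t dims[2] = { (hsize_t)nr, (hsize_t)nc };
        hid_t sp = H5Screate_simple(2, dims, NULL);
        hid_t mdcpl = notime_plist(H5P_DATASET_CREATE);
        hid_t ds = H5Dcreate2(grp, CHAR(STRING_ELT(names, i)), H5T_IEEE_F64LE,
                              sp, H5P_DEFAULT, mdcpl, H5P_DEFAULT);
        H5Pclose(mdcpl);
        chk(ds, "dataset creation");
        double *buf = (double *)R_alloc((size_t)nr * nc, sizeof(double));
        const double *v = REAL(m);
        for (int r = 0; r < nr; r++)
            for (int c = 0; c < nc; c++)
                buf[(size_t)r * nc + c] = v[r + (size_t)c * nr];
        chk(H5Dwrite(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf),
            "dataset write");
        H5Dclose(ds); H5Sclose(sp);
    }
    H5Gclose(grp);
    H5Pclose(gcpl);
    H5Fclose(file);
    return R_NilValue;
}

SEXP C_h5_read_map_file(SEXP path, SEXP group)
{
    const char *p = CHAR(STRING_ELT(path, 0));
    hid_t file = H5Fopen(p, H5F_ACC_RDONLY, H5P_DEFAULT);
    chk(file, "file open");
    hid_t grp = H5Gopen2(file, CHAR(STRING_ELT(group, 0)), H5P_DEFAULT);
    chk(grp, "group open");
    H5G_info_t info;
    H5Gget_info(grp, &info);
    int n = (int)info.nlinks;
    SEXP out = PROTECT(Rf_allocVector(VECSXP, n));
    SEXP nm = PROTECT(Rf_allocVector(STRSXP, n));
    for (int i = 0; i < n; i++) {
        char name[256];
        H5Lget_name_by_idx(grp, ".", H5_INDEX_NAME, H5_ITER_INC, (hsize_t)i,
                           name, sizeof(name), H5P_DEFAULT);
        SET_STRING_ELT(nm, i, Rf_mkChar(name));
        hid_t ds = H5Dopen2(grp, name, H5P_DEFAULT);
        chk(ds, "dataset open");
        hid_t sp = H5Dget_space(ds);
        hsize_t dims[2];
        H5Sget_simple_extent_dims(sp, dims, NULL);
        int nr = (int)dims[0], nc = (int)dims[1];
        double *buf = (double *)R_alloc((size_t)nr * nc, sizeof(double));
        chk(H5Dread(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf),
            "dataset read");
        SEXP m = PROTECT(Rf_allocMatrix(REALSXP, nr, nc));
        double *v = REAL(m);
        for (int r = 0; r < nr; r++)
            for (int c = 0; c < nc; c++)
                v[r + (size_t)c * nr] = buf[(size_t)r * nc + c];
        SET_VECTOR_ELT(out, i, m);
        UNPROTECT(1);
        H5Sclose(sp); H5Dclose(ds);
    }
    Rf_setAttrib(out, R_NamesSymbol, nm);
    H5Gclose(grp); H5Fclose(file);
    UNPROTECT(2);
    return out;
}

/* ---- image stacks -------------------------------------------------------- */

static void write_attr_list(hid_t loc, SEXP attrs)
{
    SEXP names = Rf_getAttrib(attrs, R_NamesSymbol);
    for (int i = 0; i < (int)XLENGTH(attrs); i++) {
        SEXP v = VECTOR_ELT(attrs, i);
        const char *nm = CHAR(STRING_ELT(names, i));
        if (Rf_isString(v))
            attr_string(loc, nm, CHAR(STRING_ELT(v, 0)));
        else if (Rf_isInteger(v))
            attr_int(loc, nm, INTEGER(v)[0]);
        else
            attr_double(loc, nm, Rf_asReal(v));
    }
}

SEXP C_h5_write_stack(SEXP path, SEXP chunks, SEXP dims, SEXP dtype,
                      SEXP images_per_dataset, SEXP filter_info, SEXP attrs)
{
    const char *p = CHAR(STRING_ELT(path, 0));
    int H = INTEGER(dims)[0], W = INTEGER(dims)[1];
    int n_frames = (int)XLENGTH(chunks);
    int ipd = Rf_asInteger(images_per_dataset);
    const char *dt = CHAR(STRING_ELT(dtype, 0));
    hid_t ftype = strcmp(dt, "int32") == 0 ? H5T_STD_I32LE : H5T_IEEE_F64LE;

    int filter_id = Rf_asInteger(VECTOR_ELT(filter_info, 0));
    SEXP cdv = VECTOR_ELT(filter_info, 1);

    hid_t fcpl = notime_plist(H5P_FILE_CREATE);
    hid_t file = H5Fcreate(p, H5F_ACC_TRUNC, fcpl, H5P_DEFAULT);
    H5Pclose(fcpl);
    chk(file, "file creation");
    hid_t gcpl = notime_plist(H5P_GROUP_CREATE);
    hid_t entry = H5Gcreate2(file, "entry", H5P_DEFAULT, gcpl, H5P_DEFAULT);
    attr_string(entry, "NX_class", "NXentry");
    hid_t data = H5Gcreate2(entry, "data", H5P_DEFAULT, gcpl, H5P_DEFAULT);
    attr_string(data, "NX_class", "NXdata");
    hid_t meta = H5Gcreate2(entry, "jfproc", H5P_DEFAULT, gcpl, H5P_DEFAULT);
    write_attr_list(meta, attrs);
    H5Gclose(meta);

    int n_ds = (n_frames + ipd - 1) / ipd;
    if (n_ds == 0) n_ds = 0;
    for (int d = 0; d < n_ds; d++) {
        int lo = d * ipd;                 /* 0-based frame range */
        int hi = lo + ipd > n_frames ? n_frames : lo + ipd;
        int nim = hi - lo;
        hsize_t ddims[3] = { (hsize_t)nim, (hsize_t)H, (hsize_t)W };
        hsize_t cdims[3] = { 1, (hsize_t)H, (hsize_t)W };
        hid_t sp = H5Screate_simple(3, ddims, NULL);
        hid_t dcpl = notime_plist(H5P_DATASET_CREATE);
        H5Pset_chunk(dcpl, 3, cdims);
        if (filter_id == 1) {
            H5Pset_deflate(dcpl, XLENGTH(cdv) ? (unsigned)INTEGER(cdv)[0] : 6);
        } else if (filter_id > 1) {
            unsigned cd[8];
            size_t ncd = (size_t)XLENGTH(cdv);
            for (size_t i = 0; i < ncd && i < 8; i++)
                cd[i] = (unsigned)INTEGER(cdv)[i];
            chk(H5Pset_filter(dcpl, (H5Z_filter_t)filter_id, H5Z_FLAG_MANDATORY,
                              ncd, cd), "filter setup");
        }
        char name[32];
        snprintf(name, sizeof(name), "data_%06d", d + 1);
        hid_t ds = H5Dcreate2(data, name, ftype, sp, H5P_DEFAULT, dcpl, H5P_DEFAULT);
        chk(ds, "dataset creation");
        attr_int(ds, "image_nr_low", lo + 1);
        attr_int(ds, "image_nr_high", hi);
        for (int i = lo; i < hi; i++) {
            SEXP ch = VECTOR_ELT(chunks, i);
            hsize_t off[3] = { (hsize_t)(i - lo), 0, 0 };
            chk(H5Dwrite_chunk(ds, H5P_DEFAULT, 0, off, (size_t)XLENGTH(ch),
                               RAW(ch)), "direct chunk write");
        }
        H5Dclose(ds); H5Pclose(dcpl); H5Sclose(sp);
    }
    H5Gclose(data); H5Gclose(entry); H5Pclose(gcpl); H5Fclose(file);
    return R_NilValue;
}

static SEXP read_group_attrs(hid_t loc)
{
    H5O_info2_t oinfo;
    H5Oget_info3(loc, &oinfo, H5O_INFO_NUM_ATTRS);
    int n = (int)oinfo.num_attrs;
    SEXP out = PROTECT(Rf_allocVector(VECSXP, n));
    SEXP nm = PROTECT(Rf_allocVector(STRSXP, n));
    for (int i = 0; i < n; i++) {
        char name[256];
        H5Aget_name_by_idx(loc, ".", H5_INDEX_NAME, H5_ITER_INC, (hsize_t)i,
                           name, sizeof(name), H5P_DEFAULT);
        SET_STRING_ELT(nm, i, Rf_mkChar(name));
        hid_t at = H5Aopen(loc, name, H5P_DEFAULT);
        hid_t ty = H5Aget_type(at);
        H5T_class_t cls = H5Tget_class(ty);
        if (cls == H5T_STRING) {
            size_t sz = H5Tget_size(ty);
            char *buf = (char *)R_alloc(sz + 2, 1);
            hid_t mt = H5Tcopy(H5T_C_S1);
            H5Tset_size(mt, sz + 1);
            H5Aread(at, mt, buf);
            buf[sz] = '\0';
            SET_VECTOR_ELT(out, i, Rf_mkString(buf));
            H5Tclose(mt);
        } else if (cls == H5T_INTEGER) {
            int v;
            H5Aread(at, H5T_NATIVE_INT, &v);
            SET_VECTOR_ELT(out, i, Rf_ScalarInteger(v));
        } else {
            double v;
            H5Aread(at, H5T_NATIVE_DOUBLE, &v);
            SET_VECTOR_ELT(out, i, Rf_ScalarReal(v));
        }
        H5Tclose(ty); H5Aclose(at);
    }
    Rf_setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(2);
    return out;
}

SEXP C_h5_read_stack(SEXP path)
{
    const char *p = CHAR(STRING_ELT(path, 0));
    hid_t file = H5Fopen(p, H5F_ACC_RDONLY, H5P_DEFAULT);
    chk(file, "file open");
    hid_t data = H5Gopen2(file, "/entry/data", H5P_DEFAULT);
    chk(data, "data group open");

    H5G_info_t info;
    H5Gget_info(data, &info);
    int n_ds = (int)info.nlinks;

    SEXP dsets = PROTECT(Rf_allocVector(VECSXP, n_ds));
    SEXP dsnames = PROTECT(Rf_allocVector(STRSXP, n_ds));
    int is_int = 1;
    int Hout = 0, Wout = 0;
    for (int d = 0; d < n_ds; d++) {
        char name[256];
        H5Lget_name_by_idx(data, ".", H5_INDEX_NAME, H5_ITER_INC, (hsize_t)d,
                           name, sizeof(name), H5P_DEFAULT);
        SET_STRING_ELT(dsnames, d, Rf_mkChar(name));
        hid_t ds = H5Dopen2(data, name, H5P_DEFAULT);
        chk(ds, "dataset open");
        hid_t sp = H5Dget_space(ds);
        hsize_t ddims[3];
        H5Sget_simple_extent_dims(sp, ddims, NULL);
        int nim = (int)ddims[0];
        Hout = (int)ddims[1];
        Wout = (int)ddims[2];

        hid_t ty = H5Dget_type(ds);
        is_int = H5Tget_class(ty) == H5T_INTEGER;
        H5Tclose(ty);

        hid_t dcpl = H5Dget_create_plist(ds);
        int nfilt = H5Pget_nfilters(dcpl);
        int filter_id = 0;
        unsigned cd[8];
        size_t ncd = 8;
        if (nfilt > 0) {
            unsigned flags;
            char fname[64];
            filter_id = (int)H5Pget_filter2(dcpl, 0, &flags, &ncd, cd,
                                            sizeof(fname), fname, NULL);
        } else {
            ncd = 0;
        }

        SEXP chunks = PROTECT(Rf_allocVector(VECSXP, nim));
        for (int i = 0; i < nim; i++) {
            hsize_t off[3] = { (hsize_t)i, 0, 0 };
            hsize_t csize = 0;
            chk(H5Dget_chunk_storage_size(ds, off, &csize), "chunk size query");
            SEXP ch = PROTECT(Rf_allocVector(RAWSXP, (R_xlen_t)csize));
            uint32_t filters = 0;
            chk(H5Dread_chunk(ds, H5P_DEFAULT, off, &filters, RAW(ch)),
                "direct chunk read");
            SET_VECTOR_ELT(chunks, i, ch);
            UNPROTECT(1);
        }

        int lo = 0, hi = 0;
        if (H5Aexists(ds, "image_nr_low")) {
            hid_t a = H5Aopen(ds, "image_nr_low", H5P_DEFAULT);
            H5Aread(a, H5T_NATIVE_INT, &lo);
            H5Aclose(a);
            a = H5Aopen(ds, "image_nr_high", H5P_DEFAULT);
            H5Aread(a, H5T_NATIVE_INT, &hi);
            H5Aclose(a);
        }

        SEXP entry = PROTECT(Rf_allocVector(VECSXP, 5));
        SET_VECTOR_ELT(entry, 0, chunks);
        SET_VECTOR_ELT(entry, 1, Rf_ScalarInteger(filter_id));
        SEXP cdv = PROTECT(Rf_allocVector(INTSXP, (R_xlen_t)ncd));
        for (size_t i = 0; i < ncd; i++) INTEGER(cdv)[i] = (int)cd[i];
        SET_VECTOR_ELT(entry, 2, cdv);
        SET_VECTOR_ELT(entry, 3, Rf_ScalarInteger(lo));
        SET_VECTOR_ELT(entry, 4, Rf_ScalarInteger(hi));
        SEXP enm = PROTECT(Rf_allocVector(STRSXP, 5));
        SET_STRING_ELT(enm, 0, Rf_mkChar("chunks"));
        SET_STRING_ELT(enm, 1, Rf_mkChar("filter_id"));
        SET_STRING_ELT(enm, 2, Rf_mkChar("cd_values"));
        SET_STRING_ELT(enm, 3, Rf_mkChar("image_nr_low"));
        SET_STRING_ELT(enm, 4, Rf_mkChar("image_nr_high"));
        Rf_setAttrib(entry, R_NamesSymbol, enm);
        SET_VECTOR_ELT(dsets, d, entry);
        UNPROTECT(4);
        H5Pclose(dcpl); H5Sclose(sp); H5Dclose(ds);
    }
    Rf_setAttrib(dsets, R_NamesSymbol, dsnames);

    SEXP attrs = R_NilValue;
    if (H5Lexists(file, "/entry/jfproc", H5P_DEFAULT) > 0) {
        hid_t meta = H5Gopen2(file, "/entry/jfproc", H5P_DEFAULT);
        attrs = read_group_attrs(meta);
        H5Gclose(meta);
    }
    PROTECT(attrs);

    SEXP out = PROTECT(Rf_allocVector(VECSXP, 4));
    SET_VECTOR_ELT(out, 0, dsets);
    SET_VECTOR_ELT(out, 1, Rf_mkString(is_int ? "int32" : "double"));
    SET_VECTOR_ELT(out, 2, attrs);
    SEXP odim = PROTECT(Rf_allocVector(INTSXP, 2));
    INTEGER(odim)[0] = Hout;
    INTEGER(odim)[1] = Wout;
    SET_VECTOR_ELT(out, 3, odim);
    SEXP nm = PROTECT(Rf_allocVector(STRSXP, 4));
    SET_STRING_ELT(nm, 0, Rf_mkChar("datasets"));
    SET_STRING_ELT(nm, 1, Rf_mkChar("dtype"));
    SET_STRING_ELT(nm, 2, Rf_mkChar("attrs"));
    SET_STRING_ELT(nm, 3, Rf_mkChar("dims"));
    Rf_setAttrib(out, R_NamesSymbol, nm);
    H5Gclose(data); H5Fclose(file);
    UNPROTECT(6);
    return out;
}

/* Read a whole dataset through the regular filtered H5Dread path (used as a
 * cross-check against the direct-chunk reader). */
SEXP C_h5_read_dataset_filtered(SEXP path, SEXP dset)
{
    const char *p = CHAR(STRING_ELT(path, 0));
    hid_t file = H5Fopen(p, H5F_ACC_RDONLY, H5P_DEFAULT);
    chk(file, "file open");
    hid_t ds = H5Dopen2(file, CHAR(STRING_ELT(dset, 0)), H5P_DEFAULT);
    chk(ds, "dataset open");
    hid_t sp = H5Dget_space(ds);
    hsize_t ddims[3] = {1, 1, 1};
    int rank = H5Sget_simple_extent_ndims(sp);
    H5Sget_simple_extent_dims(sp, ddims, NULL);
    size_t n = 1;
    for (int i = 0; i < rank; i++) n *= (size_t)ddims[i];
    hid_t ty = H5Dget_type(ds);
    SEXP out;
    if (H5Tget_class(ty) == H5T_INTEGER) {
        out = PROTECT(Rf_allocVector(INTSXP, (R_xlen_t)n));
        chk(H5Dread(ds, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                    INTEGER(out)), "filtered read");
    } else {
        out = PROTECT(Rf_allocVector(REALSXP, (R_xlen_t)n));
        chk(H5Dread(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                    REAL(out)), "filtered read");
    }
    SEXP dim = PROTECT(Rf_allocVector(INTSXP, rank));
    for (int i = 0; i < rank; i++) INTEGER(dim)[i] = (int)ddims[i];
    Rf_setAttrib(out, Rf_install("h5dims"), dim);
    H5Tclose(ty); H5Sclose(sp); H5Dclose(ds); H5Fclose(file);
    UNPROTECT(2);
    return out;
}
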