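"""Independent reference decoder/encoder for the bitshuffle HDF5 filter
stream, built from the documented transform (bit-plane transposition via
unpackbits/transpose/packbits) and numcodecs' LZ4/Zstd bindings.

Used by the test suite as a cross-implementation oracle:
  python bshuf_ref.py decode <elem_size> <codec>   # stdin: framed stream
  python bshuf_ref.py encode <elem_size> <codec> <block_bytes>
  python bshuf_ref.py shuffle <elem_size>          # stdin: raw elements
Results are written to stdout as raw bytes.
"""
import struct
import sys

import numpy as np
import numcodecs.lz4 as nclz4
import numcodecs.zstd as nczstd


def bitshuffle(buf: bytes, elem_size: int) -> bytes:
    arr = np.frombuffer(buf, dtype=np.uint8)
    n = arr.size // elem_size
    bits = np.unpackbits(arr).reshape(n, elem_size * 8)
    return np.packbits(bits.T.copy().reshape(-1)).tobytes()


def bitunshuffle(buf: bytes, elem_size: int) -> bytes:
    arr = np.frombuffer(buf, dtype=np.uint8)
    nbits = elem_size * 8
    n = arr.size // elem_size
    planes = np.unpackbits(arr).reshape(nbits, n)
    return np.packbits(planes.T.copy().reshape(-1)).tobytes()


def comp(block: bytes, codec: str) -> bytes:
    if codec == "lz4":
        return nclz4.compress(np.frombuffer(block, np.uint8), 1)[4:]
    return nczstd.compress(np.frombuffer(block, np.uint8), 3)


def decomp(block: bytes, n_out: int, codec: str) -> bytes:
    if codec == "lz4":
        framed = struct.pack("<I", n_out) + block
        return nclz4.decompress(framed)
    return nczstd.decompress(block)


def decode(stream: bytes, elem_size: int, codec: str, shuffle=True) -> bytes:
    total, block_bytes = struct.unpack(">QI", stream[:12])
    n_elem = total // elem_size
    block_elems = block_bytes // elem_size
    n_full, leftover = divmod(n_elem, block_elems)
    main_left = leftover - leftover % 8
    tail = (leftover % 8) * elem_size
    out = bytearray()
    pos = 12
    sizes = [block_elems] * n_full + ([main_left] if main_left else [])
    for be in sizes:
        (clen,) = struct.unpack(">I", stream[pos:pos + 4])
        pos += 4
        raw = decomp(stream[pos:pos + clen], be * elem_size, codec)
        pos += clen
        out += bitunshuffle(raw, elem_size) if shuffle else raw
    if tail:
        out += stream[pos:pos + tail]
    assert len(out) == total
    return bytes(out)


def encode(data: bytes, elem_size: int, codec: str, block_bytes: int,
           shuffle=True) -> bytes:
    n_elem = len(data) // elem_size
    block_elems = block_bytes // elem_size
    n_full, leftover = divmod(n_elem, block_elems)
    main_left = leftover - leftover % 8
    tail = (leftover % 8) * elem_size
    out = bytearray(struct.pack(">QI", len(data), block_bytes))
    pos = 0
    sizes = [block_elems] * n_full + ([main_left] if main_left else [])
    for be in sizes:
        bb = be * elem_size
        block = data[pos:pos + bb]
        pos += bb
        payload = bitshuffle(block, elem_size) if shuffle else block
        c = comp(payload, codec)
        out += struct.pack(">I", len(c)) + c
    if tail:
        out += data[pos:pos + tail]
    return bytes(out)


if __name__ == "__main__":
    mode = sys.argv[1]
    elem = int(sys.argv[2])
    data = sys.stdin.buffer.read()
    if mode == "shuffle":
        sys.stdout.buffer.write(bitshuffle(data, elem))
    elif mode == "unshuffle":
        sys.stdout.buffer.write(bitunshuffle(data, elem))
    elif mode == "decode":
        sys.stdout.buffer.write(decode(data, elem, sys.argv[3]))
    elif mode == "encode":
        sys.stdout.buffer.write(encode(data, elem, sys.argv[3],
                                       int(sys.argv[4])))
    else:
        raise SystemExit("unknown mode " + mode)
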