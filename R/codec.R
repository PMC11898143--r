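#' Binary telemetry codec for packet records
#'
#' Encodes a [packet_record()] into the compact binary wire format used
#' between node and gateway, and decodes it back. Layout (big-endian):
#'
#' * magic `0xA5` (1 byte), version (1 byte)
#' * node id, slot: unsigned 16-bit each
#' * window start: unsigned 32-bit seconds
#' * presence bitmap: 16 bits, bit *i* set when the *i*-th channel of the
#'   fixed channel order (temp, rh, sound, lux, h2s, nh3, co2, voc, nox,
#'   pm1, pm25, pm4, pm10) is present
#' * per present channel, in channel order: avg, min, max as signed 16-bit
#'   fixed point with scales temp x100, rh x100, sound x10, lux x1,
#'   h2s x100, nh3 x100, co2 x1, voc x1, nox x1, pm x10
#' * CRC-16/CCITT (poly 0x1021, init 0xFFFF) over all preceding bytes
#'
#' Decoding inverts encoding exactly on the quantized domain: values are
#' recovered at the fixed-point resolution of their channel. Quantities
#' outside the representable signed 16-bit fixed-point range are clamped at
#' encode time (notably illuminance above 32767 lx, a limitation of the
#' 16-bit layout).
#'
#' @param record A `packet_record`.
#' @param bytes A raw vector produced by `encode_packet()`.
#' @return `encode_packet()` returns a raw vector; `decode_packet()` a
#'   `packet_record`. Malformed input raises conditions of class
#'   `barnsense_bad_magic`, `barnsense_bad_checksum` or
#'   `barnsense_truncated`.
#' @examples
#' p <- packet_record(7L, 3L, 600, list(temp = c(avg = 21.52, min = 21.3, max = 21.9)))
#' identical(decode_packet(encode_packet(p)), p)
#' @export
encode_packet <- function(record) {
  if (!inherits(record, "packet_record"))
    stop_barnsense("record must be a packet_record", "barnsense_config_error")
  present <- CHANNELS %in% names(record$stats)
  bitmap <- sum(2^(which(present) - 1L))
  body <- c(as.raw(0xA5), as.raw(0x01),
            u16_bytes(record$node_id), u16_bytes(record$slot),
            u32_bytes(record$window_start), u16_bytes(bitmap))
  for (ch in CHANNELS[present]) {
    sc <- CODEC_SCALE[[ch]]
    s <- record$stats[[ch]]
    q <- pmin(32767, pmax(-32768, round(s[c("avg", "min", "max")] * sc)))
    body <- c(body, i16_bytes(q[1]), i16_bytes(q[2]), i16_bytes(q[3]))
  }
  c(body, u16_bytes(crc16_ccitt(body)))
}

#' @rdname encode_packet
#' @export
decode_packet <- function(bytes) {
  if (!is.raw(bytes)) stop_barnsense("bytes must be raw", "barnsense_config_error")
  if (length(bytes) < 14)
    stop_barnsense("buffer shorter than minimal packet", "barnsense_truncated")
  if (bytes[1] != as.raw(0xA5))
    stop_barnsense("bad magic byte", "barnsense_bad_magic")
  n <- length(bytes)
  crc_stored <- u16_value(bytes[(n - 1):n])
  if (crc16_ccitt(bytes[1:(n - 2)]) != crc_stored)
    stop_barnsense("checksum mismatch", "barnsense_bad_checksum")
  node_id <- u16_value(bytes[3:4])
  slot <- u16_value(bytes[5:6])
  window_start <- u32_value(bytes[7:10])
  bitmap <- u16_value(bytes[11:12])
  present <- which(bitwAnd(bitmap, 2^(seq_along(CHANNELS) - 1L)) > 0)
  need <- 12 + 6 * length(present) + 2
  if (n != need)
    stop_barnsense(sprintf("expected %d bytes, got %d", need, n),
                   "barnsense_truncated")
  stats <- list()
  off <- 13
  for (i in present) {
    ch <- CHANNELS[i]
    sc <- CODEC_SCALE[[ch]]
    v <- c(avg = i16_value(bytes[off:(off + 1)]),
           min = i16_value(bytes[(off + 2):(off + 3)]),
           max = i16_value(bytes[(off + 4):(off + 5)])) / sc
    stats[[ch]] <- v
    off <- off + 6
  }
  packet_record(node_id, slot, window_start, stats)
}

#' Write and read framed binary packet files
#'
#' Stores packets as consecutive length-prefixed records (unsigned 16-bit
#' big-endian length, then the encoded packet bytes).
#'
#' @param packets List of `packet_record`s.
#' @param path File path (conventionally `.pkt`).
#' @return `read_pkt()` returns the list of decoded `packet_record`s.
#' @export
write_pkt <- function(packets, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (p in packets) {
    b <- encode_packet(p)
    writeBin(u16_bytes(length(b)), con)
    writeBin(b, con)
  }
  invisible(path)
}

#' @rdname write_pkt
#' @export
read_pkt <- function(path) {
  bytes <- readBin(path, what = "raw", n = file.info(path)$size)
  out <- list()
  off <- 1L
  while (off <= length(bytes)) {
    if (off + 1L > length(bytes))
      stop_barnsense("truncated frame header", "barnsense_truncated")
    len <- u16_value(bytes[off:(off + 1L)])
    if (off + 1L + len > length(bytes))
      stop_barnsense("truncated frame body", "barnsense_truncated")
    out[[length(out) + 1L]] <- decode_packet(bytes[(off + 2L):(off + 1L + len)])
    off <- off + 2L + len
  }
  out
}

CODEC_SCALE <- list(temp = 100, rh = 100, sound = 10, lux = 1, h2s = 100,
                    nh3 = 100, co2 = 1, voc = 1, nox = 1,
                    pm1 = 10, pm25 = 10, pm4 = 10, pm10 = 10)

u16_bytes <- function(x) {
  x <- as.integer(round(x))
  as.raw(c(x %/% 256L, x %% 256L))
}

u32_bytes <- function(x) {
  x <- round(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

i16_bytes <- function(x) {
  x <- as.integer(round(x))
  if (x < 0) x <- x + 65536L
  u16_bytes(x)
}

u16_value <- function(b) as.integer(b[1]) * 256L + as.integer(b[2])

u32_value <- function(b)
  ((as.numeric(b[1]) * 256 + as.numeric(b[2])) * 256 + as.numeric(b[3])) * 256 +
  as.numeric(b[4])

i16_value <- function(b) {
  v <- u16_value(b)
  if (v >= 32768L) v - 65536L else v
}

# CRC-16/CCITT-FALSE, table driven.
crc16_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    crc <- bitwShiftL(i, 8)
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 0x8000) > 0)
        bitwXor(bitwShiftL(crc, 1), 0x1021) else bitwShiftL(crc, 1)
      crc <- bitwAnd(crc, 0xFFFF)
    }
    tab[i + 1] <- crc
  }
  tab
})

crc16_ccitt <- function(bytes) {
  crc <- 0xFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(bitwShiftR(crc, 8), b), 0xFF)
    crc <- bitwAnd(bitwXor(bitwShiftL(crc, 8), crc16_table[idx + 1]), 0xFFFF)
  }
  crc
}
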