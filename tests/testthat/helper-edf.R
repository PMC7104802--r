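# Minimal EDF writer used to build synthetic fixtures for the reader tests.
# Channels may have different sampling rates (samples per record).
write_edf_fixture <- function(path, channels, record_duration = 1,
                              n_records = 2) {
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, n) {
    s <- formatC(as.character(x), width = n, flag = "-")
    writeChar(substr(s, 1, n), con, nchars = n, eos = NULL)
  }
  ns <- length(channels)
  pad("0", 8)
  pad("patient X", 80)
  pad("recording Y", 80)
  pad("01.01.20", 8)
  pad("00.00.00", 8)
  pad(256 * (ns + 1), 8)
  pad("", 44)
  pad(n_records, 8)
  pad(record_duration, 8)
  pad(ns, 4)
  for (ch in channels) pad(ch$label, 16)
  for (ch in channels) pad("transducer", 80)
  for (ch in channels) pad("uV", 8)
  for (ch in channels) pad(ch$phys_min, 8)
  for (ch in channels) pad(ch$phys_max, 8)
  for (ch in channels) pad(ch$dig_min, 8)
  for (ch in channels) pad(ch$dig_max, 8)
  for (ch in channels) pad("", 80)
  for (ch in channels) pad(ch$spr, 8)
  for (ch in channels) pad("", 32)
  for (r in seq_len(n_records)) {
    for (ch in channels) {
      seg <- ch$digital[((r - 1) * ch$spr + 1):(r * ch$spr)]
      writeBin(as.integer(seg), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

# Build a channel spec whose digital samples encode a known physical signal
edf_channel <- function(label, phys, spr, phys_min = -1000,
                        phys_max = 1000, dig_min = -32768,
                        dig_max = 32767) {
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  digital <- round((phys - phys_min) / gain + dig_min)
  list(label = label, phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max, spr = spr,
       digital = digital,
       # quantized physical values the reader should reproduce
       physical = (digital - dig_min) * gain + phys_min)
}
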