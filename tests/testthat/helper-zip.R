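# Minimal store-only (uncompressed) ZIP writer used to build test
# archives in code; the environment provides unzip for extraction but no
# zip archiver.

crc32_table <- local({
  tab <- integer(256L)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
      } else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

write_store_zip <- function(zipfile, files) {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  con <- file(zipfile, "wb")
  on.exit(close(con))
  entries <- list()
  offset <- 0L
  for (f in files) {
    data <- readBin(f, "raw", n = file.info(f)$size)
    name <- charToRaw(basename(f))
    crc <- crc32(data)
    entries[[length(entries) + 1L]] <-
      list(name = name, crc = crc, size = length(data), offset = offset)
    u32(0x04034b50); u16(20L); u16(0L); u16(0L); u16(0L); u16(0L)
    u32(crc); u32(length(data)); u32(length(data))
    u16(length(name)); u16(0L)
    writeBin(name, con)
    writeBin(data, con)
    offset <- offset + 30L + length(name) + length(data)
  }
  cd_start <- offset
  for (e in entries) {
    u32(0x02014b50); u16(20L); u16(20L); u16(0L); u16(0L); u16(0L); u16(0L)
    u32(e$crc); u32(e$size); u32(e$size)
    u16(length(e$name)); u16(0L); u16(0L); u16(0L); u16(0L); u32(0L)
    u32(e$offset)
    writeBin(e$name, con)
    offset <- offset + 46L + length(e$name)
  }
  u32(0x06054b50); u16(0L); u16(0L)
  u16(length(entries)); u16(length(entries))
  u32(offset - cd_start); u32(cd_start); u16(0L)
  invisible(zipfile)
}
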