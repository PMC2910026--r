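#' Read a FASTA/FASTQ dataset with compression autodetection
#'
#' Detects the compression (none, gzip, zip) by magic bytes and the format
#' (FASTA vs FASTQ) by content sniffing.  Zip archives with several
#' FASTA/FASTQ members are concatenated into one dataset in member order.
#' Sequences are upper-cased, U converted to T, and IUPAC wildcard letters
#' other than N converted to N (with a message giving the count); any
#' other letter (e.g. protein data) is a validation error.  FASTQ
#' qualities are retained and dropped only when writing FASTA.
#'
#' @param path Input file.
#' @return Data frame with columns `id`, `desc`, `seq`, `qual`
#'   (`NA` for FASTA input).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 2L && magic[1L] == as.raw(0x50) && magic[2L] == as.raw(0x4b)) {
    exdir <- tempfile("tagtrimr_zip_")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
    members <- utils::unzip(path, exdir = exdir)
    members <- members[!dir.exists(members)]
    if (!length(members)) stop("zip archive contains no files", call. = FALSE)
    parts <- lapply(sort(members), read_one_sequence_file)
    return(do.call(rbind, parts))
  }
  read_one_sequence_file(path)  # gzip is handled transparently downstream
}

sniff_format <- function(path) {
  con <- gzfile(path, "rt")  # also reads plain text
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("empty input file: ", path, call. = FALSE)
    if (nzchar(trimws(line))) break
  }
  c1 <- substr(trimws(line), 1L, 1L)
  if (c1 == ">") return("fasta")
  if (c1 == "@") return("fastq")
  stop("not a FASTA or FASTQ file (first record starts with '", c1, "'): ",
       path, call. = FALSE)
}

read_one_sequence_file <- function(path) {
  fmt <- sniff_format(path)
  if (fmt == "fasta") {
    x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop("invalid FASTA file ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
    qual <- rep(NA_character_, length(x))
  } else {
    x <- tryCatch(Biostrings::readBStringSet(path, format = "fastq",
                                             with.qualities = TRUE),
                  error = function(e) {
                    stop("invalid FASTQ file ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  }
  header <- names(x)
  id <- sub("\\s.*$", "", header)
  desc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header),
                 NA_character_)
  norm <- normalize_reads(as.character(x))
  if (!is.na(norm$first_bad)) {
    stop(sprintf("record '%s' contains non-DNA letters", id[norm$first_bad]),
         call. = FALSE)
  }
  if (norm$n_converted > 0) {
    message(norm$n_converted,
            " IUPAC wildcard base(s) in the reads converted to N")
  }
  data.frame(id = id, desc = desc, seq = norm$seq, qual = qual,
             stringsAsFactors = FALSE)
}

annotate_headers <- function(records, report) {
  i <- match(records$id, report$id)
  stopifnot(!anyNA(i))
  ann <- sprintf("init_len=%d trim_len=%d trim5=%d trim3=%d mm5=%s mm3=%s frags=%d",
                 report$init_len[i], report$trim_len[i], report$trim5[i],
                 report$trim3[i] + 1L,  # 1-based first trimmed 3' position
                 ifelse(is.na(report$mm5[i]), "NA", report$mm5[i]),
                 ifelse(is.na(report$mm3[i]), "NA", report$mm3[i]),
                 report$frags[i])
  ifelse(is.na(records$desc), ann, paste(records$desc, ann))
}

#' Write pipeline results
#'
#' Writes the passing and failing streams as FASTA (default) or FASTQ
#' (when the input had qualities), optionally gzip-compressed and with
#' per-read provenance appended to the headers as space-separated
#' key=value fields: initial length, trimmed length, 5'/3' trim positions
#' (1-based at this layer), per-end mismatches and fragment count.  The
#' per-record report is written as TSV.
#'
#' @param result List from [run_pipeline()].
#' @param out_prefix Path prefix for the output files.
#' @param annotate Append provenance fields to headers.
#' @param out_format `"fasta"` or `"fastq"` (FASTQ only when qualities are
#'   present).
#' @param gzip Compress sequence outputs.
#' @return Invisible character vector of the files written.
#' @export
write_results <- function(result, out_prefix, annotate = FALSE,
                          out_format = c("fasta", "fastq"), gzip = FALSE) {
  out_format <- match.arg(out_format)
  ext <- paste0(".", out_format, if (gzip) ".gz" else "")
  files <- character(0)
  for (stream in c("passing", "failing")) {
    recs <- result[[stream]]
    f <- paste0(out_prefix, ".", stream, ext)
    if (nrow(recs)) {
      if (anyDuplicated(recs$id)) {
        stop("duplicate sequence ids in ", stream, " output", call. = FALSE)
      }
      hdr <- if (annotate) annotate_headers(recs, result$report) else
        ifelse(is.na(recs$desc), recs$id, paste(recs$id, recs$desc))
      if (annotate) hdr <- paste(recs$id, hdr)
      write_seq_file(recs, hdr, f, out_format, gzip)
    } else {
      con <- if (gzip) gzfile(f, "wt") else file(f, "wt")
      close(con)
    }
    files <- c(files, f)
  }
  rf <- paste0(out_prefix, ".report.tsv")
  utils::write.table(result$report, rf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(files, rf))
}

write_seq_file <- function(recs, headers, path, format, gzip = FALSE) {
  x <- Biostrings::DNAStringSet(recs$seq)
  names(x) <- headers
  if (format == "fastq") {
    q <- recs$qual
    if (anyNA(q)) stop("FASTQ output requires qualities for all records",
                       call. = FALSE)
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(q),
                                compress = gzip)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta", compress = gzip)
  }
  invisible(path)
}

#' Write / read a filter configuration file
#'
#' Flat JSON with one key per parameter; round-trips losslessly.  Unknown
#' keys and malformed values are rejected with the offending keys named.
#'
#' @param config A [filter_config()].
#' @param path File path.
#' @return `write_params()` the path, invisibly; `read_params()` the
#'   [filter_config()].
#' @export
write_params <- function(config, path) {
  stopifnot(inherits(config, "filter_config"))
  x <- unclass(config)
  x$max_len <- if (is.infinite(x$max_len)) "Inf" else x$max_len
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("malformed parameter file: ",
                                         conditionMessage(e), call. = FALSE))
  known <- names(formals(filter_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (identical(x$max_len, "Inf")) x$max_len <- Inf
  for (k in c("min_len", "max_len", "max_n_percent", "split_max_mm")) {
    if (!is.null(x[[k]])) {
      v <- suppressWarnings(as.numeric(x[[k]]))
      if (is.na(v)) stop("invalid value for key '", k, "': ", x[[k]],
                         call. = FALSE)
      x[[k]] <- v
    }
  }
  do.call(filter_config, x)
}

#' Write a tag-detection review table
#'
#' @param detection Result of [detect_tag()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_detection_report <- function(detection, path) {
  tab <- profile_table(detection$profile, detection$classes)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
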