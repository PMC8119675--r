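#' Read genomic intervals from a BED file
#'
#' Accepts 3 to 6 tab-separated columns (chrom, start, end, name, score,
#' strand), 0-based half-open coordinates.  Intervals are validated against
#' the genome; order is preserved.
#'
#' @param path Path to a BED file.
#' @param genome A [genome_spec()] used for validation.
#' @return A data.frame with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_intervals <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3 | ncol > 6))
    stop(sprintf("line %d: expected 3-6 tab-separated columns",
                 which(ncol < 3 | ncol > 6)[1]))
  nc <- min(ncol)
  chrom <- vapply(fields, `[[`, "", 1)
  start <- as.numeric(vapply(fields, `[[`, "", 2))
  end <- as.numeric(vapply(fields, `[[`, "", 3))
  bad <- which(!(chrom %in% genome$chroms))
  if (length(bad))
    stop(sprintf("line %d: unknown chromosome '%s'", bad[1], chrom[bad[1]]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad))
    stop(sprintf("line %d: end <= start (or unparsable coordinates)", bad[1]))
  bad <- which(start < 0 | end > genome$lengths[chrom])
  if (length(bad))
    stop(sprintf("line %d: interval outside chromosome bounds", bad[1]))
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (nc >= 4) out$name <- vapply(fields, function(f) f[4], "")
  if (nc >= 5) out$score <- suppressWarnings(
    as.numeric(vapply(fields, function(f) f[5], "")))
  if (nc >= 6) {
    strand <- vapply(fields, function(f) f[6], "")
    if (!all(strand %in% c("+", "-", ".")))
      stop("strand column must be one of '+', '-', '.'")
    out$strand <- strand
  }
  out
}

#' Assign reads to fixed-width bins by their midpoint
#'
#' Each read interval contributes one count to the bin containing its
#' midpoint `floor((start + end) / 2)`; midpoints on a bin border fall in the
#' right-hand (half-open) bin.  Reads on unknown chromosomes are an error.
#'
#' @param reads Interval data.frame (`chrom`, `start`, `end`).
#' @param genome A [genome_spec()].
#' @param bin_size Bin width in bp.
#' @return A raw `BinnedTrack`; `total_reads` is the number of reads supplied.
#'   An empty read list yields an all-zero track with `total_reads = 0`,
#'   which is flagged unusable for normalization downstream.
#' @export
bin_reads <- function(reads, genome, bin_size) {
  stopifnot(bin_size > 0)
  values <- lapply(genome$chroms, function(chrom)
    numeric(n_bins(genome, chrom, bin_size)))
  names(values) <- genome$chroms
  if (nrow(reads) > 0) {
    if (!all(reads$chrom %in% genome$chroms))
      stop("reads on chromosomes absent from the genome")
    mid <- floor((reads$start + reads$end) / 2)
    bin <- floor(mid / bin_size) + 1
    for (chrom in unique(reads$chrom)) {
      sel <- reads$chrom == chrom
      b <- bin[sel]
      b <- b[b >= 1 & b <= length(values[[chrom]])]
      tb <- tabulate(b, nbins = length(values[[chrom]]))
      values[[chrom]] <- values[[chrom]] + tb
    }
  }
  binned_track(values, genome, bin_size, units = "raw",
               total_reads = nrow(reads))
}

#' Write a binned track as bedGraph
#'
#' One record per bin, 0-based half-open, values printed to 6 significant
#' decimals.
#'
#' @param track A `BinnedTrack`.
#' @param path Output file.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in track$genome$chroms) {
    v <- track$values[[chrom]]
    nb <- length(v)
    start <- (seq_len(nb) - 1) * track$bin_size
    end <- pmin(seq_len(nb) * track$bin_size, track$genome$lengths[[chrom]])
    writeLines(sprintf("%s\t%d\t%d\t%.6f", chrom, as.integer(start),
                       as.integer(end), v), con)
  }
  invisible(path)
}

#' Read a bedGraph written by [write_track()]
#'
#' @param path bedGraph file.
#' @param genome A [genome_spec()].
#' @param bin_size Bin width used when the track was written.
#' @param units Track units to restore.
#' @param total_reads Library size to restore, if any.
#' @return A `BinnedTrack`.
#' @export
read_track <- function(path, genome, bin_size, units = "normalized",
                       total_reads = NA_real_) {
  df <- utils::read.table(path, sep = "\t", col.names =
      c("chrom", "start", "end", "value"), stringsAsFactors = FALSE)
  values <- lapply(genome$chroms, function(chrom) {
    v <- numeric(n_bins(genome, chrom, bin_size))
    sel <- df$chrom == chrom
    v[df$start[sel] / bin_size + 1] <- df$value[sel]
    v
  })
  names(values) <- genome$chroms
  binned_track(values, genome, bin_size, units = units,
               total_reads = total_reads)
}

#' Write a domain set as BED
#'
#' Columns: chrom, start, end, name, score (mean enriched posterior scaled to
#' 0-1000), status tag (`unassigned`, `conserved` or `lost`).
#'
#' @param domains Domain data.frame as returned by [connect_domains()].
#' @param path Output file.
#' @export
write_domains <- function(domains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(domains))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                       domains$chrom, as.integer(domains$start),
                       as.integer(domains$end), domains$name,
                       as.integer(round(domains$mean_posterior * 1000)),
                       domains$status), con)
  invisible(path)
}

#' Read a domain BED written by [write_domains()]
#'
#' @param path BED file.
#' @param genome A [genome_spec()].
#' @return Domain data.frame.
#' @export
read_domains <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      mean_posterior = numeric(), status = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(f, `[[`, "", 1),
    start = as.numeric(vapply(f, `[[`, "", 2)),
    end = as.numeric(vapply(f, `[[`, "", 3)),
    name = vapply(f, `[[`, "", 4),
    mean_posterior = as.numeric(vapply(f, `[[`, "", 5)) / 1000,
    status = vapply(f, `[[`, "", 6),
    stringsAsFactors = FALSE)
  if (!all(out$chrom %in% genome$chroms))
    stop("domain on chromosome absent from the genome")
  out
}

#' Read a sparse COO intrachromosomal contact matrix
#'
#' Plain-text format: optional header line `#bin_size=<bp> chrom=<name>`,
#' then rows `bin_i<TAB>bin_j<TAB>count` with 0-based bin indices at
#' `bin_size` resolution.  Upper-triangle storage is accepted and mirrored;
#' conflicting duplicate entries are an error.
#'
#' @param path COO text file.
#' @param bin_size Bin width in bp (checked against the header if present).
#' @param chrom Chromosome name (checked against the header if present).
#' @param genome A [genome_spec()] fixing the matrix dimension.
#' @return A `ContactMatrix` in `raw` state.
#' @export
read_contact_matrix <- function(path, bin_size, chrom, genome) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr)) {
    m <- regmatches(hdr[1], regexec("bin_size=(\\d+)\\s+chrom=(\\S+)", hdr[1]))[[1]]
    if (length(m) == 3) {
      if (as.numeric(m[2]) != bin_size)
        stop(sprintf("header bin_size=%s does not match %s", m[2], bin_size))
      if (m[3] != chrom)
        stop(sprintf("header chrom=%s does not match %s", m[3], chrom))
    }
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  nb <- n_bins(genome, chrom, bin_size)
  mat <- matrix(0, nb, nb)
  if (length(lines)) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    i <- as.integer(vapply(f, `[[`, "", 1))
    j <- as.integer(vapply(f, `[[`, "", 2))
    cnt <- as.numeric(vapply(f, `[[`, "", 3))
    if (any(is.na(i) | is.na(j) | is.na(cnt)))
      stop("unparsable contact record")
    if (any(i < 0 | i >= nb | j < 0 | j >= nb))
      stop("contact bin index out of range for chromosome ", chrom)
    if (any(cnt < 0))
      stop("negative contact count")
    key_fwd <- paste(pmin(i, j), pmax(i, j))
    if (anyDuplicated(key_fwd)) {
      agg <- tapply(cnt, key_fwd, function(x) length(unique(x)))
      if (any(agg > 1))
        stop("conflicting duplicate contact entries")
      keep <- !duplicated(key_fwd)
      i <- i[keep]; j <- j[keep]; cnt <- cnt[keep]
    }
    mat[cbind(i + 1, j + 1)] <- cnt
    mat[cbind(j + 1, i + 1)] <- cnt
  }
  contact_matrix(mat, chrom = chrom, bin_size = bin_size,
                 partial_bin = genome$lengths[[chrom]] %% bin_size != 0)
}

#' Write a contact matrix as sparse COO text
#'
#' Upper triangle (including the diagonal), non-zero entries only, with a
#' `#bin_size= chrom=` header.
#'
#' @param m A `ContactMatrix` (any state; raw is the interchange format).
#' @param path Output file.
#' @export
write_contact_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#bin_size=%d chrom=%s", as.integer(m$bin_size),
                     m$chrom), con)
  idx <- which(upper.tri(m$mat, diag = TRUE) & m$mat != 0, arr.ind = TRUE)
  if (nrow(idx))
    writeLines(sprintf("%d\t%d\t%.10g", idx[, 1] - 1L, idx[, 2] - 1L,
                       m$mat[idx]), con)
  invisible(path)
}

#' Read a gene annotation BED6 into a gene table
#'
#' The TSS is derived from strand: `start` for `+`, `end - 1` for `-`.
#'
#' @param path BED6 file (name column = gene id).
#' @param genome A [genome_spec()].
#' @return A data.frame `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_genes_bed <- function(path, genome) {
  iv <- read_intervals(path, genome)
  if (is.null(iv$name) || is.null(iv$strand))
    stop("gene annotation must be BED6 (name and strand required)")
  data.frame(gene_id = iv$name, chrom = iv$chrom, strand = iv$strand,
             tss = ifelse(iv$strand == "-", iv$end - 1, iv$start),
             stringsAsFactors = FALSE)
}

#' Read a differential-expression table
#'
#' Tab-separated with header; required columns `gene_id`, `contrast`,
#' `log2fc`, `de_flag` (one of `upregulated`, `downregulated`, `ns`).
#'
#' @param path TSV file.
#' @return A data.frame.
#' @export
read_de_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "contrast", "log2fc", "de_flag")
  if (!all(need %in% names(df)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$de_flag %in% c("upregulated", "downregulated", "ns")))
    stop("de_flag must be one of upregulated/downregulated/ns")
  df
}

#' Write a gene/DE table as TSV
#' @param df Data.frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
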