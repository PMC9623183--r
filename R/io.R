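## Readers and writers for the plain-text formats the pipeline touches:
## genotype TSV / minimal VCF, peak BED6+, state and blacklist BED, JASPAR
## PFM, expression / survival / GWAS / clinical TSVs, JSON stage summaries.

#' Write a genotype matrix as TSV
#'
#' Layout: variants as rows, first columns the variant metadata
#' (id, chrom, pos, ref, alt, info_score), then one column per sample with
#' dosage codes 0/1/2 and NA for missing.
#'
#' @param geno a [genotype_matrix()] object.
#' @param path output file.
#' @export
write_genotype_tsv <- function(geno, path) {
  out <- cbind(
    geno$variants,
    as.data.frame(t(geno$dosages), check.names = FALSE)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from TSV
#'
#' Inverse of [write_genotype_tsv()].
#'
#' @param path TSV produced by [write_genotype_tsv()].
#' @return a [genotype_matrix()] object.
#' @export
read_genotype_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("id", "chrom", "pos", "ref", "alt", "info_score")
  missing_meta <- setdiff(meta_cols, names(df))
  if (length(missing_meta) > 0) {
    abort("genotype TSV missing column(s): %s", paste(missing_meta, collapse = ", "))
  }
  sample_ids <- setdiff(names(df), meta_cols)
  dos <- t(as.matrix(df[, sample_ids, drop = FALSE]))
  rownames(dos) <- sample_ids
  colnames(dos) <- df$id
  genotype_matrix(dos, df[, meta_cols], sample_ids)
}

#' Read genotypes from a minimal VCF
#'
#' Accepts biallelic records with a GT field; `./.` (or `.`) is missing.
#' Phased and unphased separators are both accepted. Multi-allelic records
#' are dropped with a message.
#'
#' @param path VCF file (plain text).
#' @return a [genotype_matrix()] object.
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  biallelic <- !grepl(",", fix$ALT) & fix$ALT != "." & fix$REF != "."
  if (any(!biallelic)) {
    message(sum(!biallelic), " non-biallelic VCF record(s) dropped")
  }
  fix <- fix[biallelic, , drop = FALSE]
  gt <- gt[biallelic, , drop = FALSE]
  count_alt <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  }
  dos <- t(apply(gt, c(1, 2), count_alt))
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
    paste0(fix$CHROM, ":", fix$POS), fix$ID
  )
  colnames(dos) <- ids
  variants <- data.frame(
    id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, info_score = NA_real_,
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, variants, rownames(dos))
}

#' Write peaks as BED6+1
#'
#' Columns: chrom, start, end, name, score, strand, summit_offset
#' (summit position relative to start). Coordinates are 0-based half-open.
#'
#' @param peaks peak data.frame with chrom/start/end/name/score/summit.
#' @param path output file.
#' @export
write_peak_bed <- function(peaks, path) {
  out <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$name, score = peaks$score, strand = ".",
    summit_offset = peaks$summit - peaks$start
  )
  write.table(out, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks from BED6+1
#' @param path BED file written by [write_peak_bed()] (or any BED6+ whose
#'   seventh column is the summit offset; absent summit defaults to the
#'   interval midpoint).
#' @return peak data.frame.
#' @export
read_peak_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) abort("peak BED needs at least 4 columns, got %d", ncol(df))
  names(df)[1:4] <- c("chrom", "start", "end", "name")
  score <- if (ncol(df) >= 5) as.numeric(df[[5]]) else 0
  summit <- if (ncol(df) >= 7) {
    df$start + as.integer(df[[7]])
  } else {
    df$start + (df$end - df$start) %/% 2L
  }
  data.frame(
    chrom = as.character(df$chrom), start = as.integer(df$start),
    end = as.integer(df$end), name = as.character(df$name),
    score = score, summit = as.integer(summit), stringsAsFactors = FALSE
  )
}

#' Read a 4-column interval BED (states, blacklist, gaps)
#'
#' @param path BED file: chrom, start, end and optionally a label column.
#' @return data.frame with chrom, start, end, label.
#' @export
read_interval_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  nfield <- lengths(parts)
  bad <- which(nfield < 3)
  if (length(bad) > 0) {
    abort("malformed BED at line %d: fewer than 3 fields", bad[1])
  }
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    abort("malformed BED at line %d: non-integer coordinates",
      which(is.na(start) | is.na(end))[1])
  }
  data.frame(
    chrom = vapply(parts, `[[`, "", 1),
    start = start, end = end,
    label = ifelse(nfield >= 4, vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_, ""), NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Write a numeric matrix as TSV with row and column names
#' @param mat matrix (rows x columns), e.g. peaks x samples or genes x samples.
#' @param path output file.
#' @param rowname_header header for the rowname column.
#' @export
write_matrix_tsv <- function(mat, path, rowname_header = "id") {
  df <- data.frame(rownames(mat), as.data.frame(mat, check.names = FALSE),
    check.names = FALSE)
  names(df)[1] <- rowname_header
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix from TSV (first column = row names)
#' @param path TSV written by [write_matrix_tsv()].
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write / read a donor survival table (donor, time_days, event)
#' @param surv data.frame with donor, time_days, event columns.
#' @param path file path.
#' @export
write_survival_tsv <- function(surv, path) {
  write.table(surv[, c("donor", "time_days", "event")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("donor", "time_days", "event")
  if (!all(need %in% names(df))) {
    abort("survival TSV needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(df$time_days <= 0)) abort("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) abort("event flags must be 0/1")
  df
}

#' Read a JASPAR-format PFM file
#'
#' Accepts the JASPAR 2016+ layout: a `>ID NAME` header followed by four
#' rows `A [ 1 2 3 ]` (brackets optional, plain whitespace-separated counts
#' also accepted). Multiple motifs per file are supported.
#'
#' @param path PFM file.
#' @param pseudocount added to every count before converting to column
#'   probabilities (default 0.01).
#' @param background base composition, length-4 numeric summing to 1
#'   (default uniform).
#' @return list of [pwm()] objects named by motif id.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.01,
                            background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0) abort("no JASPAR header ('>') found in %s", path)
  out <- list()
  for (h in seq_along(headers)) {
    i <- headers[h]
    block_end <- if (h < length(headers)) headers[h + 1] - 1 else length(lines)
    hdr <- sub("^>\\s*", "", lines[i])
    motif_id <- strsplit(hdr, "\\s+")[[1]][1]
    rows <- lines[(i + 1):block_end]
    if (length(rows) < 4) abort("motif %s: expected 4 count rows", motif_id)
    counts <- matrix(0, 4, 0)
    parsed <- lapply(rows[1:4], function(r) {
      r <- gsub("\\[|\\]", " ", r)
      r <- sub("^\\s*[ACGTacgt]\\s+", " ", paste0(" ", r))
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    w <- unique(lengths(parsed))
    if (length(w) != 1) abort("motif %s: ragged count rows", motif_id)
    counts <- do.call(rbind, parsed)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[motif_id]] <- pwm(counts, motif_id = motif_id,
      pseudocount = pseudocount, background = background)
  }
  out
}

#' Write a PWM's counts in JASPAR format
#' @param x a [pwm()] object (counts are reconstructed from probabilities
#'   times 100 when the original counts are absent).
#' @param path output file.
#' @param name display name after the id in the header.
#' @export
write_jaspar_pfm <- function(x, path, name = x$motif_id) {
  counts <- x$counts %||% round(x$probabilities * 100)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(">%s %s", x$motif_id, name), con)
  for (b in c("A", "C", "G", "T")) {
    writeLines(sprintf("%s [ %s ]", b,
      paste(format(counts[b, ], trim = TRUE), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a GWAS variant list TSV
#' @param path TSV with columns variant_id, chrom, pos, trait (and
#'   optionally source).
#' @return data.frame.
#' @export
read_gwas_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos", "trait")
  if (!all(need %in% names(df))) {
    abort("GWAS TSV needs columns: %s", paste(need, collapse = ", "))
  }
  df
}

## stage sidecar: parameters + counts + seed, deterministic formatting
write_stage_summary <- function(path, stage, params, counts, seed = NULL) {
  obj <- list(stage = stage, params = params, counts = counts)
  if (!is.null(seed)) obj$seed <- seed
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Read / write FASTA sequence windows
#'
#' Thin wrappers over Biostrings for the 61-mer allele windows the motif
#' stage consumes.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
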