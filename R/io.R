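# Plain-text format glue: Ct plate CSV, genotype/truth/frequency TSV.

#' Read a Ct plate CSV
#'
#' Columns `sample_id`, `reaction_id`, `ct_specific`, `ct_internal`;
#' the instrument's `"Undetermined"` is parsed as Ct 60.
#'
#' @param path CSV file path.
#' @return Ct record data frame.
#' @export
read_ct_plate <- function(path) {
  x <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "reaction_id", "ct_specific", "ct_internal")
  if (!all(need %in% names(x)))
    stop("Ct plate must have columns ", paste(need, collapse = ", "))
  for (col in c("ct_specific", "ct_internal")) {
    v <- x[[col]]
    v[v == "Undetermined"] <- "60"
    x[[col]] <- as.numeric(v)
  }
  x
}

#' Write a Ct plate CSV
#' @param records Ct record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct_plate <- function(records, path) {
  records$ct_specific <- signif(records$ct_specific, 6)
  records$ct_internal <- signif(records$ct_internal, 6)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype (or truth) TSV
#'
#' Columns `sample_id`, `locus`, `allele1`, `allele2`.
#' @param path TSV file path.
#' @return data frame.
#' @export
read_genotype_table <- function(path) {
  x <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "locus", "allele1", "allele2")
  if (!all(need %in% names(x)))
    stop("genotype table must have columns ", paste(need, collapse = ", "))
  x
}

#' Write a genotype table TSV
#' @param genotypes data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  utils::write.table(genotypes, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genotype calls as TSV
#'
#' One row per sample: candidate list (`"a/b; c/d"`), status, mismatch
#' count and flags.
#'
#' @param calls named list of `hla_genotype_call` (see [decode_plate()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_calls <- function(calls, path) {
  df <- do.call(rbind, lapply(calls, function(cl) data.frame(
    sample_id = cl$sample_id, locus = cl$locus,
    candidates = paste(cl$candidates, collapse = "; "),
    status = cl$status, mismatch_count = cl$mismatch_count,
    flags = paste(cl$flags, collapse = ","))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a population frequency TSV
#'
#' Columns `population`, `locus`, `allele`, `frequency` (and optionally
#' `n2`).
#'
#' @param path TSV file path.
#' @return named list population -> locus -> named frequency vector.
#' @export
read_frequency_table <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE)
  need <- c("population", "locus", "allele", "frequency")
  if (!all(need %in% names(x)))
    stop("frequency table must have columns ", paste(need, collapse = ", "))
  lapply(split(x, x$population), function(p)
    lapply(split(p, p$locus), function(l)
      stats::setNames(l$frequency, l$allele)))
}

#' Write per-locus allele frequencies as TSV
#'
#' @param freqs output of [allele_frequencies()].
#' @param path output path.
#' @param population population label column value.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(freqs, path, population = "population") {
  df <- do.call(rbind, lapply(names(freqs), function(l) data.frame(
    population = population, locus = l,
    allele = names(freqs[[l]]$frequencies),
    frequency = signif(unname(freqs[[l]]$frequencies), 6),
    n2 = freqs[[l]]$n2)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
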