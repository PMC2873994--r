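#' Parse bracketed LNA notation
#'
#' Primer sequences in the source tables mark locked-nucleic-acid (LNA)
#' bases between square brackets, e.g. `"GGCTC...TTTCT[C]"`.  This strips
#' the brackets and records the 0-based positions of the LNA bases within
#' the plain sequence.
#'
#' @param raw character scalar, sequence with optional `[X]` brackets.
#' @return list with elements `sequence` (plain IUPAC string) and `lna`
#'   (integer vector of 0-based indices).
#' @examples
#' parse_lna_sequence("GGCTCYCACTCCATGAGGTATTTCT[C]")
#' @export
parse_lna_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  seq_chars <- character(0)
  lna <- integer(0)
  in_br <- FALSE
  for (ch in chars) {
    if (ch == "[") {
      if (in_br) stop("nested '[' in sequence: ", raw)
      in_br <- TRUE
    } else if (ch == "]") {
      if (!in_br) stop("unmatched ']' in sequence: ", raw)
      in_br <- FALSE
    } else {
      if (!ch %in% strsplit(IUPAC_LETTERS, "")[[1]])
        stop("invalid base '", ch, "' in sequence: ", raw)
      seq_chars <- c(seq_chars, ch)
      if (in_br) lna <- c(lna, length(seq_chars) - 1L)
    }
  }
  if (in_br) stop("unclosed '[' in sequence: ", raw)
  list(sequence = paste(seq_chars, collapse = ""), lna = lna)
}

IUPAC_LETTERS <- "ACGTRYSWKMBDHVN"

.parse_span <- function(x, file, line) {
  m <- regmatches(x, regexec("^([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 3L)
    stop("malformed location '", x, "' (", file, ", line ", line, ")")
  c(start = as.integer(m[2]), end = as.integer(m[3]))
}

#' Load a typing-panel definition file
#'
#' Reads one or more structured-text panel files (one per locus) holding
#' the primers, probes and reaction compositions of the real-time PCR-SSP
#' typing platform.  Primer sequences are stored verbatim with their
#' bracketed LNA notation and parsed on load.
#'
#' @param paths character vector of panel file paths.
#' @return an object of class `hla_panel`: a list with data frames
#'   `primers`, `probes`, `reactions`, a named list `addressed` (reaction
#'   id to addressed-allele set), a per-locus `alleles` list (sorted),
#'   plus `loci`, `reference` and `comment` metadata.
#' @seealso [hla_panel()] for the packaged default panel,
#'   [audit_panel()], [reactivity_matrix()].
#' @export
load_panel <- function(paths) {
  parts <- lapply(paths, .load_panel_file)
  panel <- list(
    loci      = vapply(parts, `[[`, "", "locus"),
    reference = unlist(lapply(parts, function(p) stats::setNames(p$reference, p$locus))),
    comment   = unlist(lapply(parts, function(p) stats::setNames(p$comment, p$locus))),
    primers   = do.call(rbind, lapply(parts, `[[`, "primers")),
    probes    = do.call(rbind, lapply(parts, `[[`, "probes")),
    reactions = do.call(rbind, lapply(parts, `[[`, "reactions")),
    addressed = do.call(c, lapply(parts, `[[`, "addressed"))
  )
  if (anyDuplicated(panel$loci))
    stop("schema error: duplicate locus across panel files")
  rownames(panel$primers) <- NULL
  rownames(panel$probes) <- NULL
  rownames(panel$reactions) <- NULL
  panel$alleles <- lapply(stats::setNames(panel$loci, panel$loci), function(l) {
    ids <- panel$reactions$id[panel$reactions$locus == l]
    sort(unique(unlist(panel$addressed[ids])))
  })
  class(panel) <- "hla_panel"
  .check_panel_integrity(panel)
  panel
}

.load_panel_file <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("integrity error: empty panel file ", path)
  comment <- if (startsWith(lines[1], "#")) lines[1] else ""
  locus <- reference <- NA_character_
  section <- ""
  primers <- list(); probes <- list(); reactions <- list(); addressed <- list()
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (l == "" || (startsWith(l, "#") && i == 1L)) next
    if (grepl("^locus:", l)) { locus <- trimws(sub("^locus:", "", l)); next }
    if (grepl("^reference:", l)) { reference <- trimws(sub("^reference:", "", l)); next }
    if (grepl("^\\[", l)) { section <- l; next }
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (section == "[primers]") {
      if (identical(f[1], "name")) next
      if (length(f) != 3L) stop("parse error (", path, ", line ", i, "): expected 3 fields")
      p <- parse_lna_sequence(f[2])
      span <- .parse_span(f[3], path, i)
      primers[[length(primers) + 1L]] <- data.frame(
        name = f[1], locus = locus, raw = f[2], sequence = p$sequence,
        lna = I(list(p$lna)),
        orientation = if (grepl("^[A-C][0-9]+F", f[1])) "forward" else "reverse",
        ref_start = span[["start"]], ref_end = span[["end"]],
        stringsAsFactors = FALSE)
    } else if (section == "[probes]") {
      if (identical(f[1], "name")) next
      if (length(f) != 5L) stop("parse error (", path, ", line ", i, "): expected 5 fields")
      span <- .parse_span(f[5], path, i)
      probes[[length(probes) + 1L]] <- data.frame(
        name = f[1], locus = locus, dye = f[2], quencher = f[3], sequence = f[4],
        ref_start = span[["start"]], ref_end = span[["end"]],
        stringsAsFactors = FALSE)
    } else if (section == "[reactions]") {
      if (identical(f[1], "id")) next
      if (length(f) != 8L) stop("parse error (", path, ", line ", i, "): expected 8 fields")
      reactions[[length(reactions) + 1L]] <- data.frame(
        id = f[1], locus = locus,
        specific_fwd = f[2], specific_rev = f[3], specific_probe = f[4],
        internal_fwd = f[5], internal_rev = f[6], internal_probe = f[7],
        stringsAsFactors = FALSE)
      addressed[[f[1]]] <- if (is.na(f[8]) || f[8] == "") character(0) else
        strsplit(f[8], ",", fixed = TRUE)[[1]]
    } else if (section != "") {
      stop("parse error (", path, ", line ", i, "): unknown section ", section)
    }
  }
  if (length(reactions) == 0L)
    stop("integrity error: no reactions in panel file ", path)
  reactions <- do.call(rbind, reactions)
  if (anyDuplicated(reactions$id))
    stop("schema error: duplicate reaction id in ", path, ": ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  list(locus = locus, reference = reference, comment = comment,
       primers = do.call(rbind, primers), probes = do.call(rbind, probes),
       reactions = reactions, addressed = addressed)
}

.check_panel_integrity <- function(panel) {
  oligo_cols <- c("specific_fwd", "specific_rev", "internal_fwd", "internal_rev")
  miss <- setdiff(unlist(panel$reactions[oligo_cols]), panel$primers$name)
  if (length(miss))
    stop("integrity error: primer(s) referenced but not defined: ",
         paste(miss, collapse = ", "))
  missp <- setdiff(unlist(panel$reactions[c("specific_probe", "internal_probe")]),
                   panel$probes$name)
  if (length(missp))
    stop("integrity error: probe(s) referenced but not defined: ",
         paste(missp, collapse = ", "))
  invisible(panel)
}

#' Packaged default typing panel
#'
#' Loads the packaged panel definition transcribed from the platform's
#' published reaction tables: 20 HLA-A, 46 HLA-B and 15 HLA-C typing
#' reactions addressing the 14 + 23 + 12 most common East African class I
#' alleles.
#'
#' @param loci which loci to load.
#' @return an `hla_panel` object.
#' @examples
#' panel <- hla_panel()
#' panel
#' @export
hla_panel <- function(loci = c("HLA-A", "HLA-B", "HLA-C")) {
  loci <- match.arg(loci, several.ok = TRUE)
  files <- system.file("extdata",
                       paste0("panel_", sub("HLA-", "hla", loci), ".txt"),
                       package = "hlassp", mustWork = TRUE)
  load_panel(files)
}

#' @export
print.hla_panel <- function(x, ...) {
  cat("Real-time PCR-SSP typing panel\n")
  for (l in x$loci) {
    ids <- x$reactions$id[x$reactions$locus == l]
    cat(sprintf("  %s: %d reactions, %d addressed alleles, %d primers, %d probes\n",
                l, length(ids), length(x$alleles[[l]]),
                sum(x$primers$locus == l), sum(x$probes$locus == l)))
  }
  invisible(x)
}

#' Serialize a panel back to its on-disk format
#'
#' Re-emits one locus of a panel in the structured-text schema read by
#' [load_panel()].  Loading then re-serializing a packaged panel file is
#' byte-identical (sequences keep their verbatim bracketed LNA notation).
#'
#' @param panel an `hla_panel`.
#' @param path output file path.
#' @param locus which locus to write (defaults to the only one present).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, locus = NULL) {
  stopifnot(inherits(panel, "hla_panel"))
  if (is.null(locus)) {
    if (length(panel$loci) != 1L) stop("panel has several loci; give `locus`")
    locus <- panel$loci
  }
  pr <- panel$primers[panel$primers$locus == locus, ]
  pb <- panel$probes[panel$probes$locus == locus, ]
  rx <- panel$reactions[panel$reactions$locus == locus, ]
  out <- c(panel$comment[[locus]],
           paste0("locus: ", locus),
           paste0("reference: ", panel$reference[[locus]]),
           "", "[primers]", "name\tsequence\tlocation",
           sprintf("%s\t%s\t%d-%d", pr$name, pr$raw, pr$ref_start, pr$ref_end),
           "", "[probes]", "name\tdye\tquencher\tsequence\tlocation",
           sprintf("%s\t%s\t%s\t%s\t%d-%d", pb$name, pb$dye, pb$quencher,
                   pb$sequence, pb$ref_start, pb$ref_end),
           "", "[reactions]",
           paste("id", "specific_fwd", "specific_rev", "specific_probe",
                 "internal_fwd", "internal_rev", "internal_probe",
                 "addressed_alleles", sep = "\t"),
           sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s", rx$id,
                   rx$specific_fwd, rx$specific_rev, rx$specific_probe,
                   rx$internal_fwd, rx$internal_rev, rx$internal_probe,
                   vapply(panel$addressed[rx$id], paste, "", collapse = ",")))
  writeLines(out, path)
  invisible(path)
}

#' Allele-by-reaction reactivity matrix
#'
#' Derives the boolean reactivity code book for one locus: cell
#' `(allele, reaction)` is `TRUE` iff the reaction's sequence-specific
#' primer set addresses the allele.  A diploid genotype's aggregate
#' pattern is the union (logical OR) of its two allele rows.
#'
#' @param panel an `hla_panel`.
#' @param locus locus name, e.g. `"HLA-A"`.
#' @return a logical matrix of class `hla_reactivity` with alleles as
#'   rows (sorted) and reactions as columns (panel order); the locus is
#'   kept in `attr(, "locus")`.
#' @examples
#' m <- reactivity_matrix(hla_panel("HLA-A"), "HLA-A")
#' colnames(m)[m["A*2902", ]]   # reactions addressing A*2902
#' @export
reactivity_matrix <- function(panel, locus) {
  stopifnot(inherits(panel, "hla_panel"))
  if (!locus %in% panel$loci) stop("unknown locus: ", locus)
  ids <- panel$reactions$id[panel$reactions$locus == locus]
  alleles <- panel$alleles[[locus]]
  m <- matrix(FALSE, nrow = length(alleles), ncol = length(ids),
              dimnames = list(alleles, ids))
  for (id in ids) m[panel$addressed[[id]], id] <- TRUE
  structure(m, locus = locus, class = c("hla_reactivity", class(m)))
}

#' Load a transcribed reactivity matrix
#'
#' Reads an allele-by-reaction reactivity table in the mark-grid layout of
#' the published pattern tables (reactions as rows, alleles as columns,
#' `X` marking reactivity).  Used for cross-checking the matrices derived
#' from the reaction compositions against the independently printed grids.
#'
#' @param path file path.
#' @param locus locus label to attach (default: inferred from reaction ids).
#' @return an `hla_reactivity` logical matrix (alleles x reactions).
#' @export
load_reactivity_matrix <- function(path, locus = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  alleles <- f[[1]][-1]
  ids <- vapply(f[-1], `[`, "", 1)
  if (is.null(locus)) locus <- sub(" .*$", "", ids[1])
  m <- matrix(FALSE, nrow = length(alleles), ncol = length(ids),
              dimnames = list(alleles, ids))
  for (r in f[-1]) {
    cells <- c(r[-1], rep("", length(alleles)))[seq_along(alleles)]
    m[cells == "X", r[1]] <- TRUE
  }
  m <- m[sort(alleles), , drop = FALSE]
  structure(m, locus = locus, class = c("hla_reactivity", "matrix", "array"))
}

.EXPECTED_CENSUS <- data.frame(
  locus = c("HLA-A", "HLA-B", "HLA-C"),
  primers = c(31L, 50L, 26L), reactions = c(20L, 46L, 15L),
  alleles = c(14L, 23L, 12L))

# reference coordinates put exon 2 below and exon 3 above this bound for
# all three loci (exon-2 spans end < 470, exon-3 spans start > 710)
.EXON_BOUNDARY <- 600L

#' Audit a typing panel
#'
#' Recomputes the panel census (primer/probe/reaction/addressed-allele
#' counts per locus) and evaluates every structural invariant of the
#' panel and its reactivity matrices.  Violations are reported, not
#' raised; verbatim-stored oddities of the printed source (a reference
#' span whose width disagrees with the primer length) are listed as flags.
#'
#' @param panel an `hla_panel`.
#' @return an object of class `hla_panel_audit`: list with `counts`
#'   (per-locus census data frame), `probes_total`, `checks` (data frame
#'   check/locus/pass/detail), `flags` (character), and `all_pass`.
#' @examples
#' audit_panel(hla_panel())
#' @export
audit_panel <- function(panel) {
  stopifnot(inherits(panel, "hla_panel"))
  counts <- do.call(rbind, lapply(panel$loci, function(l) {
    data.frame(locus = l,
               primers = sum(panel$primers$locus == l),
               probes = sum(panel$probes$locus == l),
               reactions = sum(panel$reactions$locus == l),
               alleles = length(panel$alleles[[l]]))
  }))
  checks <- list(); flags <- character(0)
  add <- function(check, locus, pass, detail = "")
    checks[[length(checks) + 1L]] <<-
      data.frame(check = check, locus = locus, pass = pass, detail = detail)

  for (l in panel$loci) {
    exp <- .EXPECTED_CENSUS[.EXPECTED_CENSUS$locus == l, ]
    if (nrow(exp)) {
      cnt <- counts[counts$locus == l, ]
      add("census", l,
          cnt$primers == exp$primers && cnt$reactions == exp$reactions &&
            cnt$alleles == exp$alleles,
          sprintf("%d primers / %d reactions / %d alleles",
                  cnt$primers, cnt$reactions, cnt$alleles))
    }
    rx <- panel$reactions[panel$reactions$locus == l, ]

    empty <- rx$id[lengths(panel$addressed[rx$id]) == 0L]
    add("addressed_nonempty", l, length(empty) == 0L,
        paste(empty, collapse = ", "))

    dyes <- panel$probes$dye[match(rx$specific_probe, panel$probes$name)]
    dyei <- panel$probes$dye[match(rx$internal_probe, panel$probes$name)]
    bad <- rx$id[dyes == dyei]
    add("two_dye_scheme", l, length(bad) == 0L, paste(bad, collapse = ", "))

    side <- function(nm)
      panel$primers$ref_start[match(nm, panel$primers$name)] < .EXON_BOUNDARY
    conv <- side(rx$specific_fwd) == side(rx$specific_rev) &
      side(rx$internal_fwd) == side(rx$internal_rev) &
      side(rx$specific_fwd) != side(rx$internal_fwd)
    add("converse_exons", l, all(conv), paste(rx$id[!conv], collapse = ", "))

    pair <- paste(rx$specific_fwd, rx$specific_rev)
    add("unique_specific_pairs", l, !anyDuplicated(pair),
        paste(rx$id[duplicated(pair)], collapse = ", "))

    m <- reactivity_matrix(panel, l)
    add("allele_in_some_reaction", l, all(rowSums(m) >= 1L),
        paste(rownames(m)[rowSums(m) < 1L], collapse = ", "))

    pr <- panel$primers[panel$primers$locus == l, ]
    lna_ok <- mapply(function(lna, seqn) {
      length(lna) == 0L || all(lna >= nchar(seqn) - 2L)
    }, pr$lna, pr$sequence)
    add("lna_near_3prime", l, all(lna_ok), paste(pr$name[!lna_ok], collapse = ", "))

    len_ok <- nchar(pr$sequence) >= 14L & nchar(pr$sequence) <= 31L
    add("primer_length_14_31", l, all(len_ok), paste(pr$name[!len_ok], collapse = ", "))

    span_bad <- pr$name[pr$ref_end - pr$ref_start + 1L != nchar(pr$sequence)]
    if (length(span_bad))
      flags <- c(flags, sprintf(
        "%s: printed reference span of %s disagrees with primer length (stored verbatim, not used in computation)",
        l, paste(span_bad, collapse = ", ")))
  }
  checks <- do.call(rbind, checks)
  res <- list(counts = counts, probes_total = nrow(panel$probes),
              addressed_total = sum(counts$alleles),
              checks = checks, flags = flags, all_pass = all(checks$pass))
  class(res) <- "hla_panel_audit"
  res
}

#' @export
print.hla_panel_audit <- function(x, ...) {
  cat("Panel audit\n")
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  %s: %d primers, %d probes, %d reactions, %d addressed alleles\n",
                x$counts$locus[i], x$counts$primers[i], x$counts$probes[i],
                x$counts$reactions[i], x$counts$alleles[i]))
  cat(sprintf("  total: %d probes, %d addressed alleles\n",
              x$probes_total, x$addressed_total))
  bad <- x$checks[!x$checks$pass, ]
  if (nrow(bad) == 0) cat("  all invariants pass\n") else
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  FAIL %s [%s]: %s\n", bad$check[i], bad$locus[i], bad$detail[i]))
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}
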