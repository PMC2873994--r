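# bitmask encoding of the IUPAC nucleotide alphabet (A=1 C=2 G=4 T=8)
.IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                 R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                 B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

.encode_iupac <- function(x) {
  m <- .IUPAC_MASK[strsplit(toupper(x), "", fixed = TRUE)[[1]]]
  if (anyNA(m)) stop("invalid nucleotide symbol in: ", x)
  unname(m)
}

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' IUPAC compatibility of a primer base with a template base
#'
#' @param primer_base single IUPAC symbol (degenerate codes allowed).
#' @param template_base single concrete base in `A`, `C`, `G`, `T`.
#' @return `TRUE` iff the template base lies in the degeneracy expansion
#'   of the primer base.
#' @examples
#' iupac_compatible("Y", "C")  # TRUE: Y = C/T
#' @export
iupac_compatible <- function(primer_base, template_base) {
  if (!template_base %in% c("A", "C", "G", "T"))
    stop("template base must be one of A/C/G/T, got: ", template_base)
  bitwAnd(.encode_iupac(primer_base), .encode_iupac(template_base)) > 0L
}

#' Matching rule set for the in-silico SSP predictor
#'
#' The platform attributes primer specificity to the 3' extreme (sharpened
#' by LNA bases), and only amplicons shorter than `max_amplicon` bases
#' amplify efficiently under the assay's cycling conditions.
#'
#' @param three_prime_exact number of 3'-terminal primer bases that must
#'   match with zero mismatches (default 3).
#' @param max_other_mismatch maximum IUPAC-incompatible positions
#'   tolerated elsewhere in the primer (default 0).
#' @param max_amplicon amplicon length bound in bp (default 250;
#'   amplicons must be strictly shorter).
#' @return list of class `ssp_rules`.
#' @export
ssp_rules <- function(three_prime_exact = 3, max_other_mismatch = 0,
                      max_amplicon = 250) {
  stopifnot(three_prime_exact >= 1, max_other_mismatch >= 0, max_amplicon > 0)
  structure(list(three_prime_exact = three_prime_exact,
                 max_other_mismatch = max_other_mismatch,
                 max_amplicon = max_amplicon), class = "ssp_rules")
}

#' Find primer annealing sites on a template
#'
#' A site is reported where the primer aligns full-length with zero
#' mismatches in its `three_prime_exact` 3'-terminal bases, exact matches
#' at every LNA position wherever it falls, and at most
#' `max_other_mismatch` IUPAC-incompatible positions elsewhere.  Minus-
#' strand sites are found by matching the primer's reverse complement.
#'
#' @param template concrete `A/C/G/T` template string (plus strand).
#' @param primer primer sequence over the IUPAC alphabet.
#' @param strand `"plus"` or `"minus"`.
#' @param three_prime_exact,max_other_mismatch see [ssp_rules()].
#' @param lna integer vector of 0-based LNA positions within the primer.
#' @return data frame with columns `start`, `end` (1-based inclusive
#'   plus-strand span of the matched footprint) and `strand`.  For a
#'   minus-strand site the primer's 3' end sits at `start` and its 5' end
#'   at `end`.
#' @export
find_primer_sites <- function(template, primer, strand = c("plus", "minus"),
                              three_prime_exact = 3, max_other_mismatch = 0,
                              lna = integer(0)) {
  strand <- match.arg(strand)
  plen <- nchar(primer)
  stopifnot(three_prime_exact >= 1, three_prime_exact <= plen)
  if (strand == "plus") {
    query <- primer
    strict <- unique(c(seq.int(plen - three_prime_exact + 1L, plen), lna + 1L))
  } else {
    query <- .revcomp(primer)
    # primer index i (1-based) maps to revcomp index plen + 1 - i
    strict <- unique(c(seq.int(1L, three_prime_exact), plen - lna))
  }
  if (any(strict < 1L | strict > plen)) stop("LNA position outside primer")
  tm <- .encode_iupac(template)
  qm <- .encode_iupac(query)
  n_off <- length(tm) - plen + 1L
  if (n_off < 1L)
    return(data.frame(start = integer(0), end = integer(0), strand = character(0)))
  other <- integer(n_off)   # mismatch count at tolerant positions
  hard <- logical(n_off)    # any mismatch at strict positions
  off <- seq_len(n_off)
  for (j in seq_len(plen)) {
    incompat <- bitwAnd(qm[j], tm[off + j - 1L]) == 0L
    if (j %in% strict) hard <- hard | incompat else other <- other + incompat
  }
  hit <- which(!hard & other <= max_other_mismatch)
  data.frame(start = hit, end = hit + plen - 1L,
             strand = rep(strand, length(hit)))
}

#' Predict amplicons for a primer pair on a template
#'
#' Pairs every plus-strand forward site with every minus-strand reverse
#' site whose 3' end lies strictly downstream of the forward 3' end, and
#' keeps pairs whose span (forward 5' end to reverse 5' end, inclusive)
#' is shorter than `max_len`.
#'
#' @inheritParams find_primer_sites
#' @param fwd_primer,rev_primer primer sequences (IUPAC).
#' @param max_len amplicon length bound (default 250; strict).
#' @param fwd_lna,rev_lna 0-based LNA positions of each primer.
#' @return data frame with columns `start`, `end`, `length` (1-based
#'   inclusive plus-strand spans).
#' @export
predict_amplicons <- function(template, fwd_primer, rev_primer, max_len = 250,
                              three_prime_exact = 3, max_other_mismatch = 0,
                              fwd_lna = integer(0), rev_lna = integer(0)) {
  fs <- find_primer_sites(template, fwd_primer, "plus",
                          three_prime_exact, max_other_mismatch, fwd_lna)
  rs <- find_primer_sites(template, rev_primer, "minus",
                          three_prime_exact, max_other_mismatch, rev_lna)
  out <- data.frame(start = integer(0), end = integer(0), length = integer(0))
  for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
    if (rs$start[j] > fs$end[i]) {          # reverse 3' end downstream
      len <- rs$end[j] - fs$start[i] + 1L
      if (len < max_len)
        out[nrow(out) + 1L, ] <- c(fs$start[i], rs$end[j], len)
    }
  }
  out
}

# exact (0-mismatch, IUPAC-compatible) probe hit fully inside [start, end],
# probe may bind either strand
.probe_within <- function(template, probe, start, end) {
  for (q in c(probe, .revcomp(probe))) {
    hits <- find_primer_sites(template, q, "plus",
                              three_prime_exact = 1, max_other_mismatch = 0)
    if (any(hits$start >= start & hits$end <= end)) return(TRUE)
  }
  FALSE
}

#' Predict the reactivity of one typing reaction on one template
#'
#' A reaction is predicted reactive when its sequence-specific primer
#' pair yields at least one amplicon under the matching rules and the
#' specific probe matches IUPAC-exactly within that amplicon; the
#' internal-standard side is evaluated analogously.
#'
#' @param template concrete allele template sequence (the first-round
#'   exon 2 - exon 3 fragment).
#' @param reaction_id reaction id in `panel`.
#' @param panel an `hla_panel`.
#' @param rules an [ssp_rules()] object.
#' @return list with logical elements `specific_reactive` and
#'   `internal_valid`.
#' @export
predict_reaction <- function(template, reaction_id, panel, rules = ssp_rules()) {
  rx <- panel$reactions[panel$reactions$id == reaction_id, ]
  if (nrow(rx) != 1L) stop("unknown reaction id: ", reaction_id)
  side <- function(fwd, rev, probe) {
    pf <- panel$primers[match(fwd, panel$primers$name), ]
    pr <- panel$primers[match(rev, panel$primers$name), ]
    pb <- panel$probes[match(probe, panel$probes$name), ]
    if (anyNA(pf$name) || anyNA(pr$name) || anyNA(pb$name))
      stop("unresolvable oligo in reaction ", reaction_id)
    amp <- predict_amplicons(template, pf$sequence, pr$sequence,
                             max_len = rules$max_amplicon,
                             three_prime_exact = rules$three_prime_exact,
                             max_other_mismatch = rules$max_other_mismatch,
                             fwd_lna = pf$lna[[1]], rev_lna = pr$lna[[1]])
    any(vapply(seq_len(nrow(amp)), function(i)
      .probe_within(template, pb$sequence, amp$start[i], amp$end[i]), TRUE))
  }
  list(specific_reactive = side(rx$specific_fwd, rx$specific_rev, rx$specific_probe),
       internal_valid = side(rx$internal_fwd, rx$internal_rev, rx$internal_probe))
}

#' Predict a reactivity matrix from allele template sequences
#'
#' Runs [predict_reaction()] for every provided allele over every
#' reaction of the locus and, when a curated matrix is supplied, reports
#' every cell on which prediction and curation disagree.
#'
#' @param allele_seqs named character vector (or `DNAStringSet`) of
#'   concrete template sequences, names are allele labels.
#' @param panel an `hla_panel`.
#' @param locus locus whose reactions to evaluate.
#' @param rules an [ssp_rules()] object.
#' @param curated optional curated `hla_reactivity` matrix to compare
#'   against (rows restricted to the provided alleles).
#' @return list with `matrix` (predicted `hla_reactivity` over the
#'   provided alleles), `internal_valid` (allele x reaction logical) and
#'   `discrepancies` (data frame `allele`, `reaction`, `predicted`,
#'   `curated`; empty when no curated matrix given or all cells agree).
#' @export
predict_matrix <- function(allele_seqs, panel, locus, rules = ssp_rules(),
                           curated = NULL) {
  allele_seqs <- vapply(as.list(allele_seqs), as.character, "")
  ids <- panel$reactions$id[panel$reactions$locus == locus]
  alleles <- names(allele_seqs)
  m <- iv <- matrix(FALSE, length(alleles), length(ids),
                    dimnames = list(alleles, ids))
  for (a in alleles) for (r in ids) {
    p <- predict_reaction(allele_seqs[[a]], r, panel, rules)
    m[a, r] <- p$specific_reactive
    iv[a, r] <- p$internal_valid
  }
  disc <- data.frame(allele = character(0), reaction = character(0),
                     predicted = logical(0), curated = logical(0))
  if (!is.null(curated)) {
    for (a in intersect(alleles, rownames(curated)))
      for (r in intersect(ids, colnames(curated)))
        if (m[a, r] != curated[a, r])
          disc[nrow(disc) + 1L, ] <- list(a, r, m[a, r], curated[a, r])
  }
  list(matrix = structure(m, locus = locus,
                          class = c("hla_reactivity", "matrix", "array")),
       internal_valid = iv, discrepancies = disc)
}
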