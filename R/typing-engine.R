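#' Reaction pattern of a single allele
#'
#' @param matrix an `hla_reactivity` matrix from [reactivity_matrix()].
#' @param allele allele name as printed in the panel (e.g. `"A*2902"`).
#' @return character vector of reaction ids (column order), the set of
#'   reactions reactive for the allele.
#' @export
allele_pattern <- function(matrix, allele) {
  if (!allele %in% rownames(matrix)) stop("unknown allele: ", allele)
  colnames(matrix)[matrix[allele, ]]
}

#' Aggregate (union) pattern of an unordered genotype
#'
#' A diploid sample reacts in every reaction reactive for either of its
#' two alleles, so a genotype's aggregate pattern is the set union of the
#' two allele patterns.  Symmetric in its arguments; for a homozygote it
#' equals the single allele's pattern.
#'
#' @inheritParams allele_pattern
#' @param allele1,allele2 allele names (order irrelevant).
#' @return character vector of reaction ids (column order).
#' @export
genotype_pattern <- function(matrix, allele1, allele2) {
  for (a in c(allele1, allele2))
    if (!a %in% rownames(matrix)) stop("unknown allele: ", a)
  colnames(matrix)[matrix[allele1, ] | matrix[allele2, ]]
}

#' Canonical label of an unordered genotype
#' @param allele1,allele2 allele names.
#' @return character, `"a1/a2"` with alleles in lexicographic order.
#' @export
genotype_label <- function(allele1, allele2) {
  paste(pmin(allele1, allele2), pmax(allele1, allele2), sep = "/")
}

# n_alleles x n_reactions logical -> n_genotypes x n_reactions logical,
# rownames are canonical genotype labels
.genotype_pattern_matrix <- function(matrix) {
  alleles <- rownames(matrix)
  idx <- which(upper.tri(diag(length(alleles)), diag = TRUE), arr.ind = TRUE)
  g <- matrix[idx[, "row"], , drop = FALSE] | matrix[idx[, "col"], , drop = FALSE]
  rownames(g) <- genotype_label(alleles[idx[, "row"]], alleles[idx[, "col"]])
  g[order(rownames(g)), , drop = FALSE]
}

#' Enumerate all unordered genotypes and their aggregate patterns
#'
#' @inheritParams allele_pattern
#' @return named list mapping the canonical genotype label (`"a1/a2"`,
#'   lexicographic, homozygotes included) to its union pattern (character
#'   vector of reaction ids); exactly `n(n+1)/2` entries for `n` alleles.
#' @examples
#' m <- reactivity_matrix(hla_panel("HLA-A"), "HLA-A")
#' length(enumerate_genotypes(m))  # 105
#' @export
enumerate_genotypes <- function(matrix) {
  g <- .genotype_pattern_matrix(matrix)
  ids <- colnames(matrix)
  lapply(stats::setNames(seq_len(nrow(g)), rownames(g)),
         function(i) ids[g[i, ]])
}

#' Uniqueness audit of the genotype code book
#'
#' Checks whether every unordered genotype of addressed alleles has a
#' distinct aggregate reactivity pattern, and lists every collision group
#' (maximal set of two or more genotypes sharing a pattern).
#'
#' @inheritParams allele_pattern
#' @return list with `n_genotypes`, `distinct_pattern_count`,
#'   `n_collision_groups` and `collision_groups` (list of sorted
#'   character vectors of genotype labels, ordered by first member).
#' @examples
#' uniqueness_audit(reactivity_matrix(hla_panel("HLA-B"), "HLA-B"))$distinct_pattern_count
#' @export
uniqueness_audit <- function(matrix) {
  g <- .genotype_pattern_matrix(matrix)
  key <- apply(g, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(rownames(g), key)
  coll <- groups[lengths(groups) > 1L]
  coll <- lapply(coll, sort)
  coll <- coll[order(vapply(coll, `[`, "", 1L))]
  names(coll) <- NULL
  list(n_genotypes = nrow(g),
       distinct_pattern_count = length(groups),
       n_collision_groups = length(coll),
       collision_groups = coll)
}

#' Call per-reaction reactivity from paired Ct values
#'
#' Each typing reaction pairs a sequence-specific amplification with an
#' internal-standardization amplification in the converse exon.  A sample
#' is positive in a reaction when delta-Ct = Ct(specific) - Ct(internal)
#' does not exceed the reaction's cutoff; a Ct of 60 encodes "threshold
#' never crossed".  The reaction is invalid when the internal standard
#' itself failed to amplify.
#'
#' @param records data frame with columns `sample_id`, `reaction_id`,
#'   `ct_specific`, `ct_internal`; Ct values must lie in `[0, 60]`.
#' @param cutoffs either a single default delta-Ct cutoff or a named
#'   numeric vector of per-reaction cutoffs (unnamed element or the
#'   `default` entry supplies the fallback).  Default 7 cycles.
#' @param internal_fail_ct internal-standard Ct at or above which the
#'   reaction is scored invalid (default 40 cycles).
#' @param reactions optional character vector of known reaction ids;
#'   records naming other reactions raise an error.
#' @return the records with added columns `delta_ct` and `status`
#'   (`"positive"`, `"negative"` or `"invalid"`).
#' @export
call_reactivity <- function(records, cutoffs = 7, internal_fail_ct = 40,
                            reactions = NULL) {
  need <- c("sample_id", "reaction_id", "ct_specific", "ct_internal")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (!is.null(reactions)) {
    unknown <- setdiff(unique(records$reaction_id), reactions)
    if (length(unknown))
      stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  }
  ct <- c(records$ct_specific, records$ct_internal)
  if (any(!is.finite(ct)) || any(ct < 0) || any(ct > 60))
    stop("Ct values must lie in [0, 60]")
  cut <- .cutoff_for(records$reaction_id, cutoffs)
  records$delta_ct <- records$ct_specific - records$ct_internal
  records$status <- ifelse(records$ct_internal >= internal_fail_ct, "invalid",
                           ifelse(records$delta_ct <= cut, "positive", "negative"))
  records
}

.cutoff_for <- function(reaction_id, cutoffs) {
  if (is.null(names(cutoffs))) {
    if (length(cutoffs) != 1L) stop("unnamed `cutoffs` must be a single default")
    return(rep(cutoffs, length(reaction_id)))
  }
  default <- if ("default" %in% names(cutoffs)) cutoffs[["default"]] else 7
  out <- unname(cutoffs[reaction_id])
  out[is.na(out)] <- default
  out
}

#' Calibrate per-reaction delta-Ct cutoffs from labeled data
#'
#' The platform's cutoffs were determined empirically; this supplies a
#' simple calibration: per reaction, the midpoint between the largest
#' delta-Ct among known positives and the smallest among known negatives.
#'
#' @param records Ct record data frame (see [call_reactivity()]).
#' @param known_reactivities data frame with columns `sample_id`,
#'   `reaction_id`, `reactive` (logical truth labels).
#' @param default_cutoff fallback cutoff for non-calibratable reactions.
#' @return data frame with columns `reaction_id`, `cutoff`, `flag`
#'   (`"ok"`, `"non_separable"`, or `"fallback"` when a class is absent).
#' @export
calibrate_cutoffs <- function(records, known_reactivities, default_cutoff = 7) {
  key <- paste(records$sample_id, records$reaction_id)
  lkey <- paste(known_reactivities$sample_id, known_reactivities$reaction_id)
  lab <- known_reactivities$reactive[match(key, lkey)]
  d <- records$ct_specific - records$ct_internal
  res <- lapply(split(seq_along(d), records$reaction_id), function(i) {
    pos <- d[i][lab[i] %in% TRUE]; neg <- d[i][lab[i] %in% FALSE]
    if (length(pos) == 0L || length(neg) == 0L)
      return(list(cutoff = default_cutoff, flag = "fallback"))
    cut <- (max(pos) + min(neg)) / 2
    list(cutoff = cut, flag = if (max(pos) >= min(neg)) "non_separable" else "ok")
  })
  data.frame(reaction_id = names(res),
             cutoff = vapply(res, `[[`, 0, "cutoff"),
             flag = vapply(res, `[[`, "", "flag"),
             row.names = NULL)
}

#' Decode an observed aggregate pattern into genotype candidates
#'
#' Matches an observed positive-reaction set against the union patterns of
#' every unordered genotype of addressed alleles, restricted to the
#' reactions that gave a valid read-out.  Exact matches are returned as
#' candidates (`"exact"`, or `"ambiguous_collision"` if the pattern is
#' shared); otherwise the nearest genotypes by symmetric-difference size
#' are returned when the minimum distance is at most `max_mismatch`
#' (`"nearest_match"`); otherwise `"no_call"`.
#'
#' @param observed character vector of positive reaction ids.
#' @param valid_reactions character vector of reactions with a valid
#'   read-out; `observed` must be a subset.
#' @param matrix an `hla_reactivity` matrix.
#' @param max_mismatch maximum tolerated symmetric-difference size for a
#'   nearest match (default 1).
#' @return object of class `hla_genotype_call`: list with `locus`,
#'   `candidates` (sorted genotype labels), `status`, `mismatch_count`,
#'   `invalid_reactions` and `flags` (subset of
#'   `homozygote_overcall_risk`, `possible_nonaddressed`, `all_negative`).
#' @export
decode <- function(observed, valid_reactions, matrix, max_mismatch = 1) {
  ids <- colnames(matrix)
  if (length(bad <- setdiff(valid_reactions, ids)))
    stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  if (length(setdiff(observed, valid_reactions)))
    stop("`observed` must be a subset of `valid_reactions`")
  valid <- intersect(ids, valid_reactions)  # column order
  res <- list(locus = attr(matrix, "locus"), candidates = character(0),
              status = "no_call", mismatch_count = NA_integer_,
              invalid_reactions = setdiff(ids, valid), flags = character(0))
  class(res) <- "hla_genotype_call"
  if (length(observed) == 0L) {
    res$flags <- "all_negative"
    return(res)
  }
  g <- .genotype_pattern_matrix(matrix)[, valid, drop = FALSE]
  obs <- valid %in% observed
  mism <- colSums(xor(t(g), obs))
  if (any(mism == 0L)) {
    res$candidates <- sort(rownames(g)[mism == 0L])
    res$status <- if (length(res$candidates) > 1L) "ambiguous_collision" else "exact"
    res$mismatch_count <- 0L
  } else if (min(mism) <= max_mismatch) {
    res$candidates <- sort(rownames(g)[mism == min(mism)])
    res$status <- "nearest_match"
    res$mismatch_count <- as.integer(min(mism))
    res$flags <- "possible_nonaddressed"
  } else {
    return(res)
  }
  homo <- vapply(strsplit(res$candidates, "/", fixed = TRUE),
                 function(p) p[1] == p[2], TRUE)
  if (any(homo)) res$flags <- c(res$flags, "homozygote_overcall_risk")
  res
}

#' @export
print.hla_genotype_call <- function(x, ...) {
  cat(sprintf("%s call: %s", x$locus, x$status))
  if (length(x$candidates))
    cat(" [", paste(x$candidates, collapse = "; "), "]", sep = "")
  if (length(x$flags)) cat(" (", paste(x$flags, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Decode a plate of reactivity calls sample by sample
#'
#' @param calls output of [call_reactivity()] for one locus.
#' @param matrix the locus's `hla_reactivity` matrix.
#' @inheritParams decode
#' @return named list of `hla_genotype_call` objects, one per sample.
#' @export
decode_plate <- function(calls, matrix, max_mismatch = 1) {
  ids <- colnames(matrix)
  if (length(bad <- setdiff(unique(calls$reaction_id), ids)))
    stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  samples <- unique(calls$sample_id)
  out <- lapply(stats::setNames(samples, samples), function(s) {
    cs <- calls[calls$sample_id == s, ]
    valid <- intersect(ids, cs$reaction_id[cs$status != "invalid"])
    observed <- intersect(ids, cs$reaction_id[cs$status == "positive"])
    d <- decode(observed, valid, matrix, max_mismatch)
    d$sample_id <- s
    d
  })
  out
}

#' Carrier-level confusion counts and Altman-Bland metrics for one allele
#'
#' A sample is a true carrier when its reference genotype contains the
#' allele, and a called carrier when every candidate genotype of its call
#' contains the allele (a conservative policy under ambiguity).
#' Sensitivity, specificity, PPV and NPV are the usual 2x2 proportions;
#' ratios with a zero denominator are reported as `NA`, not 0.
#'
#' @param calls named list of `hla_genotype_call` (see [decode_plate()]).
#' @param truth data frame with columns `sample_id`, `allele1`, `allele2`
#'   (reference genotypes; every truth sample must have a call).
#' @param allele allele to score.
#' @return one-row data frame: `allele`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` (proportions in `[0, 1]`).
#' @export
carrier_confusion <- function(calls, truth, allele) {
  missing <- setdiff(truth$sample_id, names(calls))
  if (length(missing))
    stop("truth sample(s) missing from calls: ", paste(missing, collapse = ", "))
  truth_carrier <- truth$allele1 == allele | truth$allele2 == allele
  called_carrier <- vapply(calls[as.character(truth$sample_id)], function(cl) {
    length(cl$candidates) > 0L &&
      all(vapply(strsplit(cl$candidates, "/", fixed = TRUE),
                 function(p) allele %in% p, TRUE))
  }, TRUE)
  tp <- sum(truth_carrier & called_carrier)
  fp <- sum(!truth_carrier & called_carrier)
  tn <- sum(!truth_carrier & !called_carrier)
  fn <- sum(truth_carrier & !called_carrier)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  data.frame(allele = allele, tp = tp, fp = fp, tn = tn, fn = fn,
             sensitivity = ratio(tp, tp + fn), specificity = ratio(tn, tn + fp),
             ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn))
}

#' Validation table over all addressed alleles
#'
#' Convenience wrapper computing [carrier_confusion()] for every allele of
#' the matrix.  When `exclude_collisions = TRUE`, alleles whose presence
#' is genuinely undecidable in some genotypes (i.e. alleles that differ
#' between members of a pattern-collision group) are scored only on
#' samples whose reference genotype lies outside every collision group.
#'
#' @inheritParams carrier_confusion
#' @param matrix the locus `hla_reactivity` matrix.
#' @param exclude_collisions see description (default `TRUE`).
#' @return data frame, one row per addressed allele.
#' @export
validate_typing <- function(calls, truth, matrix, exclude_collisions = TRUE) {
  truth_lab <- genotype_label(truth$allele1, truth$allele2)
  coll <- uniqueness_audit(matrix)$collision_groups
  coll_genos <- unlist(coll)
  ambiguous_alleles <- unique(unlist(lapply(coll, function(g) {
    al <- strsplit(g, "/", fixed = TRUE)
    carr <- lapply(al, unique)
    Reduce(union, carr)[!vapply(Reduce(union, carr), function(a)
      all(vapply(carr, function(x) a %in% x, TRUE)), TRUE)]
  })))
  do.call(rbind, lapply(rownames(matrix), function(a) {
    tr <- truth
    if (exclude_collisions && a %in% ambiguous_alleles)
      tr <- truth[!truth_lab %in% coll_genos, ]
    carrier_confusion(calls, tr, a)
  }))
}
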