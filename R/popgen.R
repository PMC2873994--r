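#' Allele frequencies by direct counting
#'
#' Each diploid sample contributes two allele copies per locus; the
#' frequency of an allele is its copy count over `2n`.  Samples with a
#' half-missing genotype (exactly one `NA` allele) are excluded for that
#' locus with a warning.
#'
#' @param genotypes data frame with columns `sample_id`, `locus`,
#'   `allele1`, `allele2`.
#' @return named list per locus, each a list with `frequencies` (named
#'   numeric, sums to 1), `counts`, and `n2` (number of allele copies).
#' @export
allele_frequencies <- function(genotypes) {
  if (is.null(genotypes) || nrow(genotypes) == 0L) stop("empty genotype table")
  out <- lapply(split(genotypes, genotypes$locus), function(g) {
    half <- xor(is.na(g$allele1), is.na(g$allele2))
    if (any(half)) {
      warning("excluding ", sum(half), " half-missing genotype(s) at ",
              g$locus[1])
      g <- g[!half, ]
    }
    g <- g[!is.na(g$allele1), ]
    counts <- table(c(g$allele1, g$allele2))
    counts <- counts[sort(names(counts))]
    list(frequencies = stats::setNames(as.numeric(counts) / sum(counts),
                                       names(counts)),
         counts = stats::setNames(as.integer(counts), names(counts)),
         n2 = sum(counts))
  })
  out
}

#' Carrier frequencies (fraction of samples with at least one copy)
#'
#' @inheritParams allele_frequencies
#' @return named list per locus: named numeric carrier fractions.
#' @export
carrier_frequencies <- function(genotypes) {
  if (is.null(genotypes) || nrow(genotypes) == 0L) stop("empty genotype table")
  lapply(split(genotypes, genotypes$locus), function(g) {
    g <- g[!is.na(g$allele1) & !is.na(g$allele2), ]
    alleles <- sort(unique(c(g$allele1, g$allele2)))
    vapply(stats::setNames(alleles, alleles), function(a)
      mean(g$allele1 == a | g$allele2 == a), 0)
  })
}

#' Population coverage of an addressed allele set
#'
#' @param freqs named numeric allele frequencies for one locus
#'   (normalized).
#' @param addressed character vector of addressed alleles; alleles absent
#'   from `freqs` contribute 0.
#' @return the summed frequency of the addressed alleles.
#' @export
coverage <- function(freqs, addressed) {
  sum(freqs[names(freqs) %in% addressed])
}

#' Cumulative allele-frequency curve
#'
#' Alleles sorted by decreasing frequency (ties broken lexicographically
#' by name) with their running cumulative frequency -- the layout used to
#' pick the assay's addressed-allele sets.
#'
#' @inheritParams coverage
#' @return data frame with columns `allele`, `frequency`, `cumulative`.
#' @export
cumulative_coverage_curve <- function(freqs) {
  ord <- order(-freqs, names(freqs))
  data.frame(allele = names(freqs)[ord], frequency = unname(freqs[ord]),
             cumulative = cumsum(unname(freqs[ord])))
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Guo-Thompson-style permutation scheme: the `2n` observed allele copies
#' are shuffled and re-paired into `n` genotypes; the test statistic is
#' the conditional probability of the genotype configuration given the
#' allele counts, and the p-value is the fraction of permuted
#' configurations no more probable than the observed one (with the usual
#' `+1` correction).  A monomorphic locus returns `p = 1` by convention.
#'
#' @param genotypes data frame with columns `allele1`, `allele2` (one
#'   locus), or a named numeric vector of genotype counts with names
#'   `"a1/a2"`.
#' @param n_permutations number of shuffles (default 2000, minimum 1000).
#' @param seed optional integer seed for reproducibility.
#' @return list with `p_value`, `observed_log_prob`, `n_permutations`.
#' @export
hwe_test <- function(genotypes, n_permutations = 2000, seed = NULL) {
  stopifnot(n_permutations >= 1000)
  if (is.data.frame(genotypes)) {
    keep <- !is.na(genotypes$allele1) & !is.na(genotypes$allele2)
    a1 <- genotypes$allele1[keep]; a2 <- genotypes$allele2[keep]
  } else {
    pairs <- strsplit(names(genotypes), "/", fixed = TRUE)
    a1 <- rep(vapply(pairs, `[`, "", 1L), genotypes)
    a2 <- rep(vapply(pairs, `[`, "", 2L), genotypes)
  }
  copies <- c(a1, a2)
  if (length(copies) %% 2L != 0L) stop("odd number of allele copies")
  n <- length(copies) / 2L
  if (n == 0L) stop("empty genotype table")
  if (length(unique(copies)) == 1L)
    return(list(p_value = 1, observed_log_prob = 0,
                n_permutations = n_permutations))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  log_prob <- function(a1, a2) {
    het <- sum(a1 != a2)
    gcounts <- table(paste(pmin(a1, a2), pmax(a1, a2)))
    # log conditional probability up to the configuration-independent
    # constant n! * prod(allele_count!) / (2n)!
    het * log(2) - sum(lgamma(gcounts + 1))
  }
  obs <- log_prob(a1, a2)
  hits <- 0L
  for (i in seq_len(n_permutations)) {
    s <- sample(copies)
    if (log_prob(s[seq_len(n)], s[n + seq_len(n)]) <= obs + 1e-9) hits <- hits + 1L
  }
  list(p_value = (hits + 1) / (n_permutations + 1),
       observed_log_prob = obs, n_permutations = n_permutations)
}

#' Cavalli-Sforza chord distance between two populations
#'
#' Chord measure based on square-root allele-frequency overlap, averaged
#' over loci:
#' \deqn{D^2 = \frac{4 \sum_l (1 - \sum_a \sqrt{p_{1a} p_{2a}})}{\sum_l (a_l - 1)}}
#' where \eqn{a_l} is the number of alleles observed at locus \eqn{l} in
#' either population.  Symmetric, zero iff the frequency vectors are
#' identical.
#'
#' @param freqs_1,freqs_2 named lists, locus to named numeric frequency
#'   vector (allele lists are unioned; absent alleles count 0).
#' @param loci which loci to use (default: loci shared by both).
#' @return the distance `D` (non-negative numeric scalar).
#' @export
cavalli_sforza_distance <- function(freqs_1, freqs_2, loci = NULL) {
  if (is.null(loci)) loci <- intersect(names(freqs_1), names(freqs_2))
  if (length(loci) == 0L) stop("no shared loci")
  num <- 0; den <- 0
  for (l in loci) {
    p1 <- freqs_1[[l]]; p2 <- freqs_2[[l]]
    alleles <- union(names(p1), names(p2))
    q1 <- stats::setNames(rep(0, length(alleles)), alleles); q1[names(p1)] <- p1
    q2 <- stats::setNames(rep(0, length(alleles)), alleles); q2[names(p2)] <- p2
    seen <- alleles[q1 > 0 | q2 > 0]
    num <- num + (1 - sum(sqrt(q1 * q2)))
    den <- den + (length(seen) - 1L)
  }
  if (den <= 0) return(0)
  sqrt(4 * num / den)
}

#' Pairwise chord-distance matrix over populations
#'
#' @param pop_freqs named list of populations, each a named list locus to
#'   frequency vector (see [cavalli_sforza_distance()]).
#' @param loci loci to use (default: loci common to all populations).
#' @return symmetric numeric matrix with zero diagonal, populations in
#'   the order given.
#' @export
cs_distance_matrix <- function(pop_freqs, loci = NULL) {
  pops <- names(pop_freqs)
  if (is.null(loci)) loci <- Reduce(intersect, lapply(pop_freqs, names))
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    d[i, j] <- d[j, i] <-
      cavalli_sforza_distance(pop_freqs[[i]], pop_freqs[[j]], loci)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with deterministic tie-breaking by
#' the smallest `(i, j)` index pair; negative branch lengths are clamped
#' to zero with a warning.
#'
#' @param d symmetric numeric matrix (zero diagonal) with at least three
#'   labelled rows/columns.
#' @return an unrooted `phylo` tree (class from the \pkg{ape} package).
#' @seealso [write_newick()]
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 populations")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  node <- as.list(labs)   # newick fragments
  act <- seq_len(n)
  clamped <- FALSE
  fmt <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.10g", x)
  }
  while (length(act) > 3L) {
    m <- length(act)
    dm <- d[act, act]
    r <- rowSums(dm)
    q <- (m - 2) * dm - outer(r, r, `+`)
    diag(q) <- Inf
    # smallest (i, j) pair among minima, i < j in current index order
    w <- which(q == min(q), arr.ind = TRUE)
    w <- w[w[, 1] < w[, 2], , drop = FALSE]
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE][1, ]
    i <- w[1]; j <- w[2]
    li <- dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dm[i, j] - li
    new <- sprintf("(%s:%s,%s:%s)", node[[act[i]]], fmt(li),
                   node[[act[j]]], fmt(lj))
    dnew <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    d <- rbind(cbind(d, c(dnew[match(seq_len(nrow(d)), act)])),
               c(dnew[match(seq_len(nrow(d)), act)], 0))
    d[is.na(d)] <- 0
    node[[nrow(d)]] <- new
    act <- c(act[-c(i, j)], nrow(d))
  }
  dm <- d[act, act]
  l1 <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
  l2 <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
  l3 <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", node[[act[1]]], fmt(l1),
                 node[[act[2]]], fmt(l2), node[[act[3]]], fmt(l3))
  if (clamped) warning("negative branch length(s) clamped to 0")
  ape::read.tree(text = nwk)
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` object.
#' @param path output file (newick text ending in `;` plus newline).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-D^2/2`, eigendecomposes, and scales eigenvectors by
#' the square roots of the positive eigenvalues.  Axis signs are fixed so
#' that the largest-magnitude loading on each axis is positive.  Negative
#' eigenvalues are reported but yield no coordinate axes.
#'
#' @param d symmetric distance matrix.
#' @param n_axes number of axes to return (default: all positive ones).
#' @return list with `coordinates` (populations x axes), `eigenvalues`,
#'   and `variance` (fraction of positive-eigenvalue variance per axis).
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-9 & e$values > 0)
  if (is.null(n_axes)) n_axes <- length(pos) else n_axes <- min(n_axes, length(pos))
  ax <- pos[seq_len(n_axes)]
  coords <- e$vectors[, ax, drop = FALSE] %*%
    diag(sqrt(e$values[ax]), nrow = length(ax))
  for (k in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = e$values,
       variance = e$values[pos] / sum(e$values[pos]))
}

#' Default allele alias map for cross-dataset comparison
#'
#' `Cw*0210` is treated as synonymous with `Cw*0202`, and the HLA-C
#' alleles that serology-era datasets rarely resolve are collapsed into
#' their conventional `G` groups.
#'
#' @return named character vector, allele to group label.
#' @export
default_allele_aliases <- function() {
  c("Cw*0210" = "Cw*0202",
    "Cw*0401" = "Cw*0401G", "Cw*0501" = "Cw*0501G", "Cw*0701" = "Cw*0701G",
    "Cw*0704" = "Cw*0704G", "Cw*1701" = "Cw*1701G", "Cw*1801" = "Cw*1801G")
}

#' Collapse aliased alleles in a frequency vector
#'
#' Frequencies of aliased alleles are summed into their group label;
#' total mass is conserved.  Aliases are resolved transitively; a cycle
#' is an error.
#'
#' @param freqs named numeric allele frequencies (one locus), or a named
#'   list of such vectors per locus.
#' @param alias_map named character vector, allele to replacement label
#'   (default [default_allele_aliases()]).
#' @return object of the same shape with aliases collapsed.
#' @export
alias_alleles <- function(freqs, alias_map = default_allele_aliases()) {
  if (is.list(freqs)) return(lapply(freqs, alias_alleles, alias_map = alias_map))
  resolve <- function(a) {
    seen <- character(0)
    while (a %in% names(alias_map)) {
      if (a %in% seen) stop("alias cycle at: ", a)
      seen <- c(seen, a)
      a <- alias_map[[a]]
    }
    a
  }
  target <- vapply(names(freqs), resolve, "")
  out <- tapply(freqs, target, sum)
  stats::setNames(as.numeric(out), names(out))[sort(unique(target))]
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by full hypergeometric enumeration: the sum of
#' the probabilities of all tables with the observed margins that are no
#' more probable than the observed table.
#'
#' @param tab 2x2 nonnegative integer matrix.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L))
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0L || r1 == n || c1 == 0L || c1 == n) return(1)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  lp <- stats::dhyper(support, c1, n - c1, r1, log = TRUE)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1, log = TRUE)
  sum(exp(lp[lp <= obs + 1e-7]))
}

#' Fisher-Freeman-Halton test for an r x c table (Monte-Carlo)
#'
#' Extension of the Fisher exact test to larger tables, estimated by
#' Monte-Carlo sampling of tables with the observed margins
#' (via [stats::r2dtable()]); seeded and reproducible.
#'
#' @param tab nonnegative integer matrix.
#' @param n_mc number of sampled tables (default 10000).
#' @param seed optional integer seed.
#' @return list with `p_value` and `n_mc`.
#' @export
fisher_freeman_halton <- function(tab, n_mc = 10000, seed = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  if (all(dim(tab) == 2L))
    return(list(p_value = fisher_exact_2x2(tab), n_mc = 0L))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  lp <- function(m) -sum(lgamma(m + 1))   # table log-probability up to margin constant
  obs <- lp(tab)
  sims <- stats::r2dtable(n_mc, rowSums(tab), colSums(tab))
  hits <- sum(vapply(sims, lp, 0) <= obs + 1e-9)
  list(p_value = (hits + 1) / (n_mc + 1), n_mc = n_mc)
}
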