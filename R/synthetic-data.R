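#' Ct noise model for plate simulation
#'
#' Defaults emulate the bimodal carrier / non-carrier separation seen in
#' the assay: reactive reactions amplify within a cycle of the internal
#' standard, non-reactive reactions mostly never cross the threshold
#' (Ct 60) and otherwise trail it by ~15 cycles, leaving the two classes
#' separated by well over 8 standard deviations at a delta-Ct cutoff of 7.
#'
#' @param internal_ct_mean,internal_ct_sd internal-standard Ct
#'   distribution (cycles; defaults 24, 0.7).
#' @param reactive_delta_mean,reactive_delta_sd delta-Ct distribution of
#'   reactive reactions (defaults 1, 0.5).
#' @param nonreactive_undetermined_prob probability a non-reactive
#'   reaction never crosses the threshold (Ct 60; default 0.8).
#' @param nonreactive_delta_mean,nonreactive_delta_sd delta-Ct of
#'   non-reactive reactions that do amplify late (defaults 15, 2).
#' @param dropout_prob per-reaction probability the internal standard
#'   fails (Ct 60; default 0).
#' @param seed optional integer seed used by [simulate_ct_plate()].
#' @return list of class `hla_noise_model`.
#' @export
noise_model <- function(internal_ct_mean = 24, internal_ct_sd = 0.7,
                        reactive_delta_mean = 1, reactive_delta_sd = 0.5,
                        nonreactive_undetermined_prob = 0.8,
                        nonreactive_delta_mean = 15, nonreactive_delta_sd = 2,
                        dropout_prob = 0, seed = NULL) {
  stopifnot(internal_ct_sd >= 0, reactive_delta_sd >= 0,
            nonreactive_delta_sd >= 0,
            nonreactive_undetermined_prob >= 0,
            nonreactive_undetermined_prob <= 1,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(as.list(environment()), class = "hla_noise_model")
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  expr
}

#' Simulate a population of genotypes under Hardy-Weinberg equilibrium
#'
#' Each sample's two allele copies per locus are drawn independently from
#' the supplied frequencies (random union of gametes); the two alleles
#' are stored in lexicographic order (unordered genotype).
#'
#' @param freqs named list locus to named numeric frequency vector
#'   (each summing to 1 within `1e-6`), or a single named vector (taken
#'   as one locus named `"locus"`).
#' @param n_samples number of diploid samples.
#' @param seed optional integer seed; identical seeds give identical
#'   tables.
#' @return data frame with columns `sample_id`, `locus`, `allele1`,
#'   `allele2`.
#' @export
simulate_population <- function(freqs, n_samples, seed = NULL) {
  stopifnot(n_samples >= 1)
  if (!is.list(freqs)) freqs <- list(locus = freqs)
  for (l in names(freqs))
    if (abs(sum(freqs[[l]]) - 1) > 1e-6)
      stop("frequencies for ", l, " do not sum to 1")
  .with_seed(seed, {
    ids <- sprintf("S%04d", seq_len(n_samples))
    do.call(rbind, lapply(names(freqs), function(l) {
      f <- freqs[[l]]
      a1 <- sample(names(f), n_samples, replace = TRUE, prob = f)
      a2 <- sample(names(f), n_samples, replace = TRUE, prob = f)
      data.frame(sample_id = ids, locus = l,
                 allele1 = pmin(a1, a2), allele2 = pmax(a1, a2))
    }))
  })
}

#' Simulate a Ct plate for genotyped samples
#'
#' For every sample-by-reaction combination of one locus: the internal
#' standard Ct is drawn from its normal model (or set to 60 on dropout);
#' if the sample's union pattern contains the reaction, the specific Ct
#' trails the internal Ct by the reactive delta, otherwise it is 60 with
#' probability `nonreactive_undetermined_prob` and trails by the late
#' non-reactive delta otherwise.  All Ct values are clipped to `[0, 60]`.
#'
#' @param genotypes data frame (`sample_id`, `locus`, `allele1`,
#'   `allele2`); rows of other loci than the matrix's are ignored.
#' @param matrix the locus `hla_reactivity` matrix; every genotype allele
#'   must be addressed (present as a row).
#' @param noise an [noise_model()] object (its `seed` drives all draws).
#' @return Ct record data frame: `sample_id`, `reaction_id`,
#'   `ct_specific`, `ct_internal`.
#' @export
simulate_ct_plate <- function(genotypes, matrix, noise = noise_model()) {
  locus <- attr(matrix, "locus")
  g <- genotypes[genotypes$locus == locus, ]
  if (nrow(g) == 0L) stop("no genotypes for locus ", locus)
  bad <- setdiff(unique(c(g$allele1, g$allele2)), rownames(matrix))
  if (length(bad))
    stop("allele(s) missing from matrix: ", paste(bad, collapse = ", "))
  ids <- colnames(matrix)
  .with_seed(noise$seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      pat <- matrix[g$allele1[i], ] | matrix[g$allele2[i], ]
      n <- length(ids)
      ct_int <- stats::rnorm(n, noise$internal_ct_mean, noise$internal_ct_sd)
      drop <- stats::runif(n) < noise$dropout_prob
      ct_int[drop] <- 60
      ct_spec <- numeric(n)
      ct_spec[pat] <- ct_int[pat] +
        stats::rnorm(sum(pat), noise$reactive_delta_mean, noise$reactive_delta_sd)
      und <- stats::runif(n) < noise$nonreactive_undetermined_prob
      late <- ct_int + stats::rnorm(n, noise$nonreactive_delta_mean,
                                    noise$nonreactive_delta_sd)
      ct_spec[!pat] <- ifelse(und[!pat], 60, late[!pat])
      data.frame(sample_id = g$sample_id[i], reaction_id = ids,
                 ct_specific = pmin(pmax(ct_spec, 0), 60),
                 ct_internal = pmin(pmax(ct_int, 0), 60))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Noise-free deterministic noise model
#'
#' Convenience wrapper: all standard deviations zero, non-reactive
#' reactions always undetermined, no dropout.  Under this model the
#' simulated plate is an exact rendering of the code book.
#'
#' @inheritParams noise_model
#' @return an `hla_noise_model`.
#' @export
noise_free <- function(seed = NULL) {
  noise_model(internal_ct_sd = 0, reactive_delta_sd = 0,
              nonreactive_undetermined_prob = 1, nonreactive_delta_sd = 0,
              dropout_prob = 0, seed = seed)
}

#' Build a small synthetic typing panel for in-silico tests
#'
#' Generates a toy single-locus panel whose reactions use distinct random
#' concrete primers and probes (plus one shared internal-standard set),
#' suitable as the `panel fragment` argument of [make_fixture_alleles()].
#' Addressed-allele sets are placeholders and carry no meaning here.
#'
#' @param n_reactions number of typing reactions.
#' @param seed integer seed.
#' @param locus locus label (default `"TOY"`).
#' @return an `hla_panel`.
#' @export
toy_panel <- function(n_reactions = 4, seed = 1, locus = "TOY") {
  .with_seed(seed, {
    rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    primers <- list(); probes <- list(); reactions <- list(); addressed <- list()
    addp <- function(name, seqn, start, orient)
      primers[[length(primers) + 1L]] <<- data.frame(
        name = name, locus = locus, raw = seqn, sequence = seqn,
        lna = I(list(integer(0))), orientation = orient,
        ref_start = start, ref_end = start + nchar(seqn) - 1L)
    for (k in seq_len(n_reactions)) {
      addp(sprintf("TF%02d", k), rand(20), 10L, "forward")
      addp(sprintf("TR%02d", k), rand(20), 150L, "reverse")
      probes[[length(probes) + 1L]] <- data.frame(
        name = sprintf("TP%02d", k), locus = locus, dye = "FAM",
        quencher = "BHQ1", sequence = rand(24), ref_start = 60L, ref_end = 83L)
    }
    addp("TIF01", rand(20), 400L, "forward")
    addp("TIR01", rand(20), 540L, "reverse")
    probes[[length(probes) + 1L]] <- data.frame(
      name = "TIP01", locus = locus, dye = "TET", quencher = "BHQ1",
      sequence = rand(24), ref_start = 450L, ref_end = 473L)
    for (k in seq_len(n_reactions)) {
      id <- sprintf("%s %03d", locus, k)
      reactions[[length(reactions) + 1L]] <- data.frame(
        id = id, locus = locus,
        specific_fwd = sprintf("TF%02d", k), specific_rev = sprintf("TR%02d", k),
        specific_probe = sprintf("TP%02d", k),
        internal_fwd = "TIF01", internal_rev = "TIR01", internal_probe = "TIP01")
      addressed[[id]] <- paste0("T*", sprintf("%04d", k))
    }
    panel <- list(loci = locus,
                  reference = stats::setNames("synthetic", locus),
                  comment = stats::setNames("# synthetic toy panel", locus),
                  primers = do.call(rbind, primers),
                  probes = do.call(rbind, probes),
                  reactions = do.call(rbind, reactions),
                  addressed = addressed)
    panel$alleles <- stats::setNames(
      list(sort(unique(unlist(addressed)))), locus)
    class(panel) <- "hla_panel"
    panel
  })
}

#' Engineer synthetic allele templates realizing a target reactivity matrix
#'
#' For each allele (row of `target`), builds a concrete template carrying
#' the specific forward-primer site, probe site and reverse-primer site
#' of every reaction marked `TRUE`, and the same layout with the forward
#' primer's 3'-terminal base mutated to an incompatible base for
#' reactions marked `FALSE`; the internal-standard sites are always
#' intact.  Blocks are padded so that no cross-reaction amplicon shorter
#' than the length bound can form.
#'
#' @param target logical matrix, alleles (rows) by reaction ids (columns
#'   of `panel`'s locus).
#' @param panel the panel fragment supplying the oligos (see
#'   [toy_panel()]).
#' @param seed integer seed for pad sequence.
#' @param rules [ssp_rules()] the templates should be evaluated under.
#' @param fasta optional path: write the templates as FASTA.
#' @return named character vector of template sequences.
#' @export
make_fixture_alleles <- function(target, panel, seed = 1, rules = ssp_rules(),
                                 fasta = NULL) {
  locus <- panel$loci[1]
  rx <- panel$reactions[panel$reactions$locus == locus, ]
  if (!all(colnames(target) %in% rx$id))
    stop("target columns must be reaction ids of the panel")
  # unrealizable targets: two reactions with identical oligo triples but
  # conflicting cells cannot be realized on one template
  trip <- paste(rx$specific_fwd, rx$specific_rev, rx$specific_probe)
  for (a in rownames(target)) {
    for (t in unique(trip[duplicated(trip)])) {
      cells <- target[a, rx$id[trip == t]]
      if (length(unique(cells)) > 1L)
        stop("unrealizable target: reactions sharing oligos disagree for ", a)
    }
  }
  pick <- function(mask_char) {
    # first concrete base compatible with an IUPAC symbol
    c("A", "C", "G", "T")[which(bitwAnd(.IUPAC_MASK[mask_char],
                                        c(1L, 2L, 4L, 8L)) > 0L)][1]
  }
  concretize <- function(seqn)
    paste(vapply(strsplit(seqn, "")[[1]], pick, ""), collapse = "")
  mismatch_base <- function(sym) {
    ok <- c("A", "C", "G", "T")[bitwAnd(.IUPAC_MASK[sym], c(1L, 2L, 4L, 8L)) == 0L]
    if (length(ok) == 0L)
      stop("unrealizable target: cannot mismatch fully degenerate 3' base")
    ok[1]
  }
  block_len <- max(260L, rules$max_amplicon + 10L)
  .with_seed(seed, {
    pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    build_block <- function(fwd, rev, probe, reactive) {
      f <- concretize(fwd)
      if (!reactive) {
        last <- substr(fwd, nchar(fwd), nchar(fwd))
        substr(f, nchar(f), nchar(f)) <- mismatch_base(last)
      }
      core <- paste0(f, pad(12), concretize(probe), pad(12),
                     .revcomp(concretize(rev)))
      paste0(core, pad(block_len - nchar(core)))
    }
    seqs <- vapply(rownames(target), function(a) {
      blocks <- vapply(colnames(target), function(id) {
        r <- rx[rx$id == id, ]
        build_block(panel$primers$sequence[match(r$specific_fwd, panel$primers$name)],
                    panel$primers$sequence[match(r$specific_rev, panel$primers$name)],
                    panel$probes$sequence[match(r$specific_probe, panel$probes$name)],
                    target[a, id])
      }, "")
      r <- rx[1, ]
      internal <- build_block(
        panel$primers$sequence[match(r$internal_fwd, panel$primers$name)],
        panel$primers$sequence[match(r$internal_rev, panel$primers$name)],
        panel$probes$sequence[match(r$internal_probe, panel$probes$name)],
        TRUE)
      paste(c(blocks, internal), collapse = "")
    }, "")
    if (!is.null(fasta)) {
      dss <- Biostrings::DNAStringSet(seqs)
      Biostrings::writeXStringSet(dss, fasta)
    }
    seqs
  })
}
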