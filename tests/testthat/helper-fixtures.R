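# Shared fixtures: the packaged panel and its per-locus matrices, loaded once.
panel_all <- hla_panel()
mat_by_locus <- lapply(
  stats::setNames(panel_all$loci, panel_all$loci),
  function(l) reactivity_matrix(panel_all, l)
)

# uniform HWE frequencies over the addressed alleles of a locus
uniform_freqs <- function(locus) {
  a <- panel_all$alleles[[locus]]
  list(stats::setNames(rep(1 / length(a), length(a)), a)) |>
    stats::setNames(locus)
}

# small hand-made reactivity matrix for unit tests
tiny_matrix <- function() {
  m <- matrix(c(TRUE, FALSE, TRUE,
                FALSE, TRUE, TRUE,
                TRUE, TRUE, FALSE),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("X*01", "X*02", "X*03"),
                              c("R1", "R2", "R3")))
  structure(m, locus = "X", class = c("hla_reactivity", "matrix", "array"))
}

as_reactivity <- function(m, locus) {
  structure(m, locus = locus, class = c("hla_reactivity", "matrix", "array"))
}
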