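test_that("allele patterns match the published grid rows", {
  mA <- mat_by_locus[["HLA-A"]]
  expect_equal(allele_pattern(mA, "A*0205"),
               paste("HLA-A", c("002", "003", "011", "017", "018")))
  expect_equal(allele_pattern(mA, "A*0101"),
               paste("HLA-A", c("007", "012", "018")))
  empty <- as_reactivity(matrix(FALSE, 1, 2, dimnames = list("Z*01", c("R1", "R2"))), "Z")
  expect_length(allele_pattern(empty, "Z*01"), 0L)
})

test_that("genotype patterns are unions, symmetric, idempotent on homozygotes", {
  mA <- mat_by_locus[["HLA-A"]]
  expect_equal(genotype_pattern(mA, "A*0101", "A*0205"),
               paste("HLA-A", c("002", "003", "007", "011", "012", "017", "018")))
  expect_equal(genotype_pattern(mA, "A*2902", "A*2902"),
               allele_pattern(mA, "A*2902"))
  mB <- mat_by_locus[["HLA-B"]]
  expect_equal(genotype_pattern(mB, "B*4201", "B*4202"),
               genotype_pattern(mB, "B*4201", "B*4201"))
  # property: symmetry and union-size bound over random pairs
  set.seed(7)
  for (i in 1:25) {
    ab <- sample(rownames(mB), 2)
    p12 <- genotype_pattern(mB, ab[1], ab[2])
    expect_equal(p12, genotype_pattern(mB, ab[2], ab[1]))
    expect_lte(length(p12), length(allele_pattern(mB, ab[1])) +
                 length(allele_pattern(mB, ab[2])))
  }
  expect_error(genotype_pattern(mA, "A*0101", "A*9999"), "unknown allele")
})

test_that("genotype enumeration has n(n+1)/2 entries", {
  expect_length(enumerate_genotypes(mat_by_locus[["HLA-A"]]), 105L)
  expect_length(enumerate_genotypes(mat_by_locus[["HLA-B"]]), 276L)
  expect_length(enumerate_genotypes(mat_by_locus[["HLA-C"]]), 78L)
  one <- as_reactivity(matrix(TRUE, 1, 1, dimnames = list("Z*01", "R1")), "Z")
  expect_length(enumerate_genotypes(one), 1L)
})

test_that("uniqueness audit reproduces the published collision structure", {
  uA <- uniqueness_audit(mat_by_locus[["HLA-A"]])
  expect_equal(uA$distinct_pattern_count, 105L)
  expect_length(uA$collision_groups, 0L)

  uC <- uniqueness_audit(mat_by_locus[["HLA-C"]])
  expect_equal(uC$distinct_pattern_count, 78L)
  expect_length(uC$collision_groups, 0L)

  uB <- uniqueness_audit(mat_by_locus[["HLA-B"]])
  expect_equal(uB$n_genotypes, 276L)
  expect_equal(uB$distinct_pattern_count, 273L)
  expect_equal(uB$collision_groups, list(
    c("B*0702/B*4201", "B*0702/B*4202"),
    c("B*4201/B*4201", "B*4201/B*4202"),
    c("B*4201/B*8101", "B*4202/B*8101")))
})

test_that("pattern-count conservation holds on every locus", {
  for (l in panel_all$loci) {
    u <- uniqueness_audit(mat_by_locus[[l]])
    expect_equal(u$distinct_pattern_count +
                   sum(lengths(u$collision_groups) - 1L),
                 u$n_genotypes, label = l)
  }
})

test_that("decode inverts genotype_pattern outside collision groups (brute force)", {
  for (l in panel_all$loci) {
    m <- mat_by_locus[[l]]
    pats <- enumerate_genotypes(m)
    coll <- unlist(uniqueness_audit(m)$collision_groups)
    for (g in names(pats)) {
      d <- decode(pats[[g]], colnames(m), m)
      if (g %in% coll) {
        expect_equal(d$status, "ambiguous_collision")
        expect_true(g %in% d$candidates)
      } else {
        expect_equal(d$status, "exact")
        expect_equal(d$candidates, g)
      }
    }
  }
})

test_that("decode handles worked examples, homozygote flag, empty pattern", {
  mA <- mat_by_locus[["HLA-A"]]
  d <- decode(c("HLA-A 001", "HLA-A 013"), colnames(mA), mA)
  expect_equal(d$status, "exact")
  expect_equal(d$candidates, "A*2902/A*2902")
  expect_true("homozygote_overcall_risk" %in% d$flags)

  mB <- mat_by_locus[["HLA-B"]]
  d <- decode(paste("HLA-B", c("004", "015", "016", "018", "025", "027", "037")),
              colnames(mB), mB)
  expect_equal(d$status, "ambiguous_collision")
  expect_equal(d$candidates, c("B*4201/B*4201", "B*4201/B*4202"))

  d <- decode(character(0), colnames(mA), mA)
  expect_equal(d$status, "no_call")
  expect_length(d$candidates, 0L)
  expect_equal(d$flags, "all_negative")
})

test_that("decode nearest-match and no_call behave under the mismatch bound", {
  mA <- mat_by_locus[["HLA-A"]]
  # corrupt one reaction of A*0101/A*0101 = {007, 012, 018}
  d <- decode(paste("HLA-A", c("007", "012")), colnames(mA), mA, max_mismatch = 1)
  expect_equal(d$status, "nearest_match")
  expect_equal(d$mismatch_count, 1L)
  expect_true("A*0101/A*0101" %in% d$candidates)
  expect_true("possible_nonaddressed" %in% d$flags)
  d0 <- decode(paste("HLA-A", c("007", "012")), colnames(mA), mA, max_mismatch = 0)
  expect_equal(d0$status, "no_call")
})

test_that("restricting valid reactions can only grow the exact candidate set", {
  m <- mat_by_locus[["HLA-A"]]
  pats <- enumerate_genotypes(m)
  set.seed(11)
  for (i in 1:20) {
    g <- sample(names(pats), 1)
    valid <- sample(colnames(m), 15)
    full <- decode(pats[[g]], colnames(m), m)$candidates
    restr <- decode(intersect(pats[[g]], valid), valid, m)$candidates
    expect_true(all(full %in% restr))
  }
})

test_that("carrier discriminability holds for all but B*4201/B*4202", {
  for (l in panel_all$loci) {
    m <- mat_by_locus[[l]]
    pats <- enumerate_genotypes(m)
    key <- vapply(pats, paste, "", collapse = "|")
    carriers <- function(a) grepl(a, names(pats), fixed = TRUE)
    for (a in rownames(m)) {
      shared <- intersect(key[carriers(a)], key[!carriers(a)])
      if (a %in% c("B*4201", "B*4202"))
        expect_gt(length(shared), 0L)
      else
        expect_length(shared, 0L)
    }
  }
})

test_that("call_reactivity applies the delta-Ct and internal-failure contracts", {
  rec <- data.frame(sample_id = "s1",
                    reaction_id = c("R1", "R2", "R3"),
                    ct_specific = c(25.1, 60, 30),
                    ct_internal = c(24.6, 24.0, 60))
  out <- call_reactivity(rec, cutoffs = 7, internal_fail_ct = 40)
  expect_equal(out$delta_ct, c(0.5, 36, -30))
  expect_equal(out$status, c("positive", "negative", "invalid"))

  # per-reaction cutoff override with default fallback
  out2 <- call_reactivity(rec[1:2, ], cutoffs = c("R2" = 40, default = 7))
  expect_equal(out2$status, c("positive", "positive"))

  expect_error(call_reactivity(transform(rec, ct_specific = c(61, 60, 30))),
               "\\[0, 60\\]")
  expect_error(call_reactivity(rec, reactions = c("R1", "R2")), "unknown reaction.*R3")
})

test_that("cutoff calibration finds midpoints and flags degenerate classes", {
  rec <- data.frame(sample_id = paste0("s", 1:4),
                    reaction_id = "R1",
                    ct_specific = 24 + c(0.4, 1.1, 12.0, 36.0),
                    ct_internal = 24)
  lab <- data.frame(sample_id = paste0("s", 1:4), reaction_id = "R1",
                    reactive = c(TRUE, TRUE, FALSE, FALSE))
  cal <- calibrate_cutoffs(rec, lab)
  expect_equal(cal$cutoff, 6.55)
  expect_equal(cal$flag, "ok")

  lab2 <- lab; lab2$reactive <- c(TRUE, FALSE, TRUE, FALSE)  # pos max 12 > neg min 1.1
  expect_equal(calibrate_cutoffs(rec, lab2)$flag, "non_separable")

  lab3 <- lab; lab3$reactive <- FALSE
  cal3 <- calibrate_cutoffs(rec, lab3)
  expect_equal(cal3$flag, "fallback")
  expect_equal(cal3$cutoff, 7)
})

test_that("carrier confusion computes Altman-Bland proportions with NA contracts", {
  m <- mat_by_locus[["HLA-A"]]
  # perfect concordance scenario
  truth <- data.frame(sample_id = paste0("s", 1:4),
                      allele1 = c("A*0201", "A*0201", "A*0101", "A*0301"),
                      allele2 = c("A*0201", "A*0301", "A*2902", "A*0301"))
  calls <- lapply(seq_len(nrow(truth)), function(i)
    structure(list(sample_id = truth$sample_id[i], locus = "HLA-A",
                   candidates = genotype_label(truth$allele1[i], truth$allele2[i]),
                   status = "exact", mismatch_count = 0L,
                   invalid_reactions = character(0), flags = character(0)),
              class = "hla_genotype_call"))
  names(calls) <- truth$sample_id
  cc <- carrier_confusion(calls, truth, "A*0201")
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 2, fp = 0, tn = 2, fn = 0))
  expect_equal(unlist(cc[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))

  # zero true carriers: sensitivity undefined (NA), specificity defined
  cc2 <- carrier_confusion(calls, truth, "A*3002")
  expect_true(is.na(cc2$sensitivity))
  expect_equal(cc2$specificity, 1)

  # a miss drops sensitivity to 9/10
  truth10 <- data.frame(sample_id = paste0("t", 1:10),
                        allele1 = "A*0101", allele2 = "A*0201")
  calls10 <- lapply(1:10, function(i)
    structure(list(sample_id = paste0("t", i), locus = "HLA-A",
                   candidates = if (i == 1) "A*0201/A*0201" else "A*0101/A*0201",
                   status = "exact", mismatch_count = 0L,
                   invalid_reactions = character(0), flags = character(0)),
              class = "hla_genotype_call"))
  names(calls10) <- paste0("t", 1:10)
  expect_equal(carrier_confusion(calls10, truth10, "A*0101")$sensitivity, 0.9)

  expect_error(carrier_confusion(calls, rbind(truth,
    data.frame(sample_id = "zz", allele1 = "A*0101", allele2 = "A*0101")),
    "A*0101"), "missing from calls.*zz")
})

test_that("ambiguous calls count as carrier only when all candidates agree", {
  truth <- data.frame(sample_id = "s1", allele1 = "B*4201", allele2 = "B*4202")
  amb <- list(s1 = structure(list(
    sample_id = "s1", locus = "HLA-B",
    candidates = c("B*4201/B*4201", "B*4201/B*4202"),
    status = "ambiguous_collision", mismatch_count = 0L,
    invalid_reactions = character(0), flags = character(0)),
    class = "hla_genotype_call"))
  expect_equal(carrier_confusion(amb, truth, "B*4201")$tp, 1)   # in all candidates
  expect_equal(carrier_confusion(amb, truth, "B*4202")$fn, 1)   # conservative miss
})
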