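# small deterministic table used across blocks
mk_table <- function() {
  m <- rbind(metA = c(2, 4, 6, 8),
             metB = c(1, 1, 2, 2),
             metC = c(10, 20, 30, 40))
  colnames(m) <- c("y1", "y2", "o1", "o2")
  metabolite_table(m, c("young", "young", "aged", "aged"))
}

test_that("normalization divides by the population (divisor-n) SD", {
  got <- normalize_intensity(c(2, 4, 6))
  s <- sqrt(8 / 3)
  expect_equal(got, c(2, 4, 6) / s)
  expect_equal(round(got, 4), c(1.2247, 2.4495, 3.6742))
  expect_error(normalize_intensity(c(3, 3, 3)), "degenerate")
  expect_error(normalize_intensity(5), "at least two")

  # population SD of any normalized column is exactly 1
  set.seed(2)
  for (i in 1:20) {
    x <- rlnorm(sample(3:12, 1), 10, 1)
    z <- normalize_intensity(x)
    expect_equal(sqrt(mean((z - mean(z))^2)), 1)
  }
})

test_that("table normalization flags and excludes degenerate metabolites", {
  m <- rbind(ok = c(1, 2, 3), flat = c(5, 5, 5))
  colnames(m) <- c("a", "b", "c")
  tab <- metabolite_table(m, c("g1", "g1", "g2"))
  expect_warning(norm <- normalize_table(tab), "flat")
  expect_identical(rownames(norm$intensities), "ok")
  expect_identical(attr(norm, "excluded"), "flat")
  expect_true(norm$normalized)
  expect_error(normalize_table(norm), "already normalized")
})

test_that("pathway intensity sums detected members and reports detection", {
  norm <- normalize_table(mk_table())
  one <- pathway_intensity(norm, "metA", "young")
  expect_equal(as.numeric(one),
               mean(colSums(norm$intensities["metA", 1:2, drop = FALSE])))
  two <- pathway_intensity(norm, c("metA", "metB"), "young")
  expect_equal(as.numeric(two),
               as.numeric(pathway_intensity(norm, "metA", "young")) +
                 as.numeric(pathway_intensity(norm, "metB", "young")))
  # missing member skipped but counted
  part <- pathway_intensity(norm, c("metA", "metB", "metZ"), "aged")
  expect_equal(attr(part, "detected"), c(k = 2, m = 3))
  expect_error(pathway_intensity(norm, "metZ", "young"), "no pathway member")
  expect_error(pathway_intensity(mk_table(), "metA", "young"), "normalized")

  # additivity over a disjoint partition of the metabolite set
  whole <- pathway_intensity(norm, c("metA", "metB", "metC"), "aged")
  parts <- as.numeric(pathway_intensity(norm, c("metA", "metC"), "aged")) +
    as.numeric(pathway_intensity(norm, "metB", "aged"))
  expect_equal(as.numeric(whole), parts)
})

test_that("median fold change uses group medians with zero-median flagging", {
  tab <- mk_table()
  expect_equal(as.numeric(median_fold_change(tab, "young", "young")),
               rep(1, 3))
  fc <- median_fold_change(tab, "young", "aged")
  expect_equal(unname(fc["metA"]), 7 / 3)
  expect_equal(unname(fc["metC"]), 35 / 15)

  # odd/even replicate counts against a sort-based median oracle
  set.seed(14)
  for (reps in c(3, 4, 5, 6)) {
    m <- matrix(rlnorm(2 * 2 * reps, 8, 0.5), nrow = 2)
    rownames(m) <- c("m1", "m2")
    colnames(m) <- sprintf("s%d", seq_len(2 * reps))
    tb <- metabolite_table(m, rep(c("a", "b"), each = reps))
    fc2 <- median_fold_change(tb, "a", "b")
    sort_med <- function(x) {
      s <- sort(x); n <- length(s)
      if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    }
    expect_equal(unname(fc2["m1"]),
                 unname(sort_med(m[1, (reps + 1):(2 * reps)]) /
                          sort_med(m[1, 1:reps])))
  }

  mz <- rbind(z = c(0, 0, 1, 2))
  colnames(mz) <- c("a1", "a2", "b1", "b2")
  tz <- metabolite_table(mz, c("a", "a", "b", "b"))
  fz <- median_fold_change(tz, "a", "b")
  expect_true(is.na(fz["z"]))
  expect_identical(attr(fz, "undefined"), "z")
})

mk_iso <- function(int_by_iso, samples = c("s1", "s2")) {
  df <- data.frame(metabolite_id = "glucose",
                   isotopologue = seq_along(int_by_iso) - 1)
  for (s in samples) df[[s]] <- int_by_iso
  isotopologue_table(df)
}

test_that("isotopologue sums and labeling fractions", {
  iso <- mk_iso(c(7, 0, 0, 0, 0, 0, 93))
  expect_equal(unname(isotopologue_sum(iso, "glucose")), c(100, 100))
  expect_equal(unname(isotopologue_sum(iso, "glucose", labeled_only = TRUE)),
               c(93, 93))
  expect_equal(unname(labeling_fraction(iso, "glucose")), c(93, 93))

  all_labeled <- mk_iso(c(0, 0, 0, 0, 0, 0, 100))
  expect_equal(unname(labeling_fraction(all_labeled, "glucose")), c(100, 100))
  unlabeled <- mk_iso(c(50))
  expect_equal(unname(labeling_fraction(unlabeled, "glucose")), c(0, 0))

  expect_error(isotopologue_sum(iso, "lactate"), "not present")

  # random long table against a plain loop oracle
  set.seed(15)
  mets <- c("pyr", "lac", "cit")
  df <- expand.grid(metabolite_id = mets, isotopologue = 0:3,
                    stringsAsFactors = FALSE)
  df$s1 <- rpois(nrow(df), 50); df$s2 <- rpois(nrow(df), 50)
  it <- isotopologue_table(df)
  for (m in mets) {
    want <- c(s1 = 0, s2 = 0)
    for (r in seq_len(nrow(df)))
      if (df$metabolite_id[r] == m && df$isotopologue[r] >= 1)
        want <- want + c(df$s1[r], df$s2[r])
    expect_equal(isotopologue_sum(it, m, labeled_only = TRUE), want)
  }
})

test_that("percent-pathway-remaining aggregates labeled medians and is scale invariant", {
  set.seed(16)
  mets <- c("g6p", "f16bp", "pyr")
  mk <- function(scale_per_met, reps = 4) {
    df <- expand.grid(metabolite_id = mets, isotopologue = 0:3,
                      stringsAsFactors = FALSE)
    base <- rep(scale_per_met[df$metabolite_id], 1)
    for (r in seq_len(reps))
      df[[sprintf("r%d", r)]] <- base * (df$isotopologue + 1) *
        runif(nrow(df), 0.95, 1.05)
    isotopologue_table(df)
  }
  sc <- c(g6p = 100, f16bp = 40, pyr = 250)
  young <- mk(sc)

  expect_equal(pathway_remaining_pct(young, young, mets), 100)

  # aged exactly half of young everywhere
  half <- young
  half$data[half$samples] <- lapply(half$data[half$samples], `/`, 2)
  expect_equal(pathway_remaining_pct(young, half, mets), 50)

  # heterogeneous decline: hand-computed sum of labeled medians
  aged <- mk(c(g6p = 60, f16bp = 10, pyr = 200))
  level <- function(iso) sum(vapply(mets, function(m)
    median(isotopologue_sum(iso, m, labeled_only = TRUE)), numeric(1)))
  expect_equal(pathway_remaining_pct(young, aged, mets),
               100 * level(aged) / level(young))

  # scale invariance
  y10 <- young; y10$data[y10$samples] <- lapply(y10$data[y10$samples], `*`, 10)
  a10 <- aged; a10$data[a10$samples] <- lapply(a10$data[a10$samples], `*`, 10)
  expect_equal(pathway_remaining_pct(y10, a10, mets),
               pathway_remaining_pct(young, aged, mets))

  # alternative aggregation is exposed and differs in general
  alt <- pathway_remaining_pct(young, aged, mets,
                               aggregate = "median_of_sums")
  expect_true(is.finite(alt))
})

test_that("metabolite and isotopologue TSV readers reconstruct the containers", {
  f <- withr::local_tempfile(); g <- withr::local_tempfile()
  writeLines(c("metabolite_id\ty1\ty2\to1",
               "metA\t2\t4\t6", "metB\t1\t1\t2"), f)
  writeLines(c("sample_id\tgroup", "y1\tyoung", "y2\tyoung", "o1\taged"), g)
  tab <- read_metabolite_table(f, g)
  expect_equal(dim(tab$intensities), c(2, 3))
  expect_equal(unname(tab$groups), c("young", "young", "aged"))

  p <- withr::local_tempfile()
  writeLines(c("pathway_id\tmetabolite_id",
               "glycolysis\tmetA", "glycolysis\tmetB", "tca\tmetC"), p)
  pw <- read_pathway_table(p)
  expect_equal(pw$glycolysis, c("metA", "metB"))

  i <- withr::local_tempfile()
  writeLines(c("metabolite_id\tisotopologue\ts1",
               "glucose\t0\t7", "glucose\t6\t93"), i)
  iso <- read_isotopologue_table(i)
  expect_equal(unname(labeling_fraction(iso, "glucose")), 93)
})
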