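toy_plan <- function(order = "deletions_first") {
  rearrangement_plan(
    inversion = genomic_intervals("chrT", 2000, 5000),
    deletions = genomic_intervals("chrT", c(1000, 3000), c(1100, 3050)),
    order = order)
}

test_that("an empty plan is the identity and inversions mirror endpoints", {
  empty <- rearrangement_plan()
  expect_equal(map_position(0:50, empty), 0:50)
  inv_only <- rearrangement_plan(genomic_intervals("chrT", 100, 200))
  # endpoints map to each other's positions (mirror symmetry)
  expect_equal(map_position(100, inv_only), 199)
  expect_equal(map_position(199, inv_only), 100)
  expect_equal(map_position(c(99, 200), inv_only), c(99, 200))
  # double application is the identity
  p <- 0:300
  expect_equal(map_position(map_position(p, inv_only), inv_only), p)
})

test_that("map_position is a bijection on surviving bases (exhaustive)", {
  for (ord in c("deletions_first", "inversion_first")) {
    plan <- toy_plan(ord)
    pos <- 0:9999
    img <- map_position(pos, plan)
    deleted <- is.na(img)
    expect_equal(sum(deleted), 150)  # the two deletions
    surv <- img[!deleted]
    expect_false(anyDuplicated(surv) > 0)
    # image is the contiguous shrunken axis
    expect_setequal(surv, 0:(10000 - 150 - 1))
    # analytic inverse round-trips every surviving base
    back <- invert_position_map(surv, plan)
    expect_equal(sort(back), sort(pos[!deleted]))
    expect_equal(map_position(back, plan), surv)
  }
})

test_that("random plans on toy chromosomes stay bijective", {
  for (seed in 1:5) {
    plan <- with_seed_test(seed, {
      s <- sort(sample.int(800, 4))
      rearrangement_plan(
        inversion = genomic_intervals("chrT", s[2], s[3] + 100),
        deletions = genomic_intervals("chrT", c(s[1], s[4] + 120),
                                      c(s[1] + 10, s[4] + 140)))
    })
    img <- map_position(0:999, plan)
    surv <- img[!is.na(img)]
    expect_false(anyDuplicated(surv) > 0)
    expect_equal(length(surv), 1000 - 30)  # deletions of 10 and 20 bp
  }
})

test_that("apply_rearrangement remaps, splits, and conserves bases", {
  # identity plan leaves features unchanged
  feats <- locus_features(c("e", "b", "gA", "gB"),
                          c("enhancer", "boundary", "gene_body",
                            "promoter_tss"),
                          "chrT", c(100, 2100, 2500, 6000),
                          c(300, 2200, 3500, 6200),
                          strand = c("*", "*", "+", "+"))
  idplan <- rearrangement_plan()
  same <- apply_rearrangement(feats, idplan)
  expect_equal(as.data.frame(same$features)[, c("start", "end")],
               as.data.frame(feats)[, c("start", "end")])
  expect_true(all(same$report$status == "intact"))
  # gene straddling the inversion edge is split with bp conserved
  plan <- rearrangement_plan(genomic_intervals("chrT", 3000, 5000))
  res <- apply_rearrangement(feats, plan)
  rep_gA <- res$report[res$report$name == "gA", ]
  expect_equal(rep_gA$status, "split")
  expect_equal(rep_gA$bp_out, rep_gA$bp_in)
  parts <- res$features[grepl("^gA_part", res$features$name), ]
  expect_equal(nrow(parts), 2)
  # the inverted part flips strand, the outside part keeps it
  expect_setequal(parts$strand, c("+", "-"))
  # total bp conserved minus deletions
  plan_del <- toy_plan()
  res2 <- apply_rearrangement(feats, plan_del)
  lost <- sum(res2$report$bp_in) - sum(res2$report$bp_out)
  # only bases inside deletions are lost
  overlap_del <- function(f, d) {
    sum(pmax(0, pmin(f$end, d$end) - pmax(f$start, d$start)))
  }
  expected_lost <- sum(vapply(seq_len(nrow(feats)), function(i)
    overlap_del(feats[i, ], plan_del$deletions), 0))
  expect_equal(lost, expected_lost)
  # a feature fully inside a deletion is dropped
  doomed <- locus_features("doomed", "other", "chrT", 3010, 3040)
  resd <- apply_rearrangement(doomed, plan_del)
  expect_equal(resd$report$status, "dropped")
  expect_null(resd$features)
})

test_that("inverting a region across the boundary reorders the locus", {
  # enhancer | boundary | geneA | geneB; invert boundary+geneA
  feats <- locus_features(c("enh", "bnd", "geneA", "geneB"),
                          c("enhancer", "boundary", "promoter_tss",
                            "promoter_tss"),
                          "chrT", c(100, 1000, 2000, 3000),
                          c(200, 1100, 2100, 3100))
  plan <- rearrangement_plan(genomic_intervals("chrT", 900, 2900))
  res <- apply_rearrangement(feats, plan)
  f <- res$features
  mid <- function(n) (f$start[f$name == n] + f$end[f$name == n]) / 2
  # geneA now sits between the enhancer and the boundary
  expect_true(mid("enh") < mid("geneA"))
  expect_true(mid("geneA") < mid("bnd"))
  oc <- res$order_changes
  expect_true(oc$flipped[oc$feature == "geneA" & oc$boundary == "bnd"])
  expect_false(oc$flipped[oc$feature == "enh" & oc$boundary == "bnd"])
})

test_that("double inversion is the identity on all features", {
  feats <- locus_features(c("e", "b", "g"),
                          c("enhancer", "boundary", "gene_body"),
                          "chrT", c(100, 1500, 2500), c(300, 1600, 3200),
                          strand = c("*", "*", "-"))
  plan <- rearrangement_plan(genomic_intervals("chrT", 1000, 4000))
  once <- apply_rearrangement(feats, plan)
  twice <- apply_rearrangement(once$features, plan)
  expect_equal(as.data.frame(twice$features)[, c("name", "start", "end",
                                                 "strand")],
               as.data.frame(feats)[, c("name", "start", "end", "strand")])
})

test_that("contact prediction blocks on boundaries, never on distance alone", {
  toy <- toy_rearranged_locus()
  wt <- predict_contacts(toy$features)
  wt_de_a <- wt[wt$enhancer == "DE" & wt$promoter == "geneA_promoter", ]
  wt_de_b <- wt[wt$enhancer == "DE" & wt$promoter == "geneB_promoter", ]
  expect_true(wt_de_a$allowed)
  expect_false(wt_de_b$allowed)
  expect_equal(wt_de_b$blocking, "boundary")
  # the rearrangement flips both predictions, although the newly allowed
  # contact spans a LONGER distance than the blocked wild-type one
  res <- apply_rearrangement(toy$features, toy$plan)
  mut <- predict_contacts(res$features)
  mut_de_a <- mut[mut$enhancer == "DE" & mut$promoter == "geneA_promoter", ]
  mut_de_b <- mut[mut$enhancer == "DE" & mut$promoter == "geneB_promoter", ]
  expect_false(mut_de_a$allowed)
  expect_true(mut_de_b$allowed)
  # the de novo allowed contact spans more bp than the wild-type blocked
  # separation of the same pair
  expect_gt(mut_de_b$separation, wt_de_b$separation)
  # no boundaries, infinite range: everything allowed
  open_feats <- toy$features[toy$features$kind != "boundary", ]
  expect_true(all(predict_contacts(open_feats)$allowed))
  # touching a boundary does not block
  touch <- locus_features(c("e", "b", "p"),
                          c("enhancer", "boundary", "promoter_tss"),
                          "chrT", c(0, 1000, 2000), c(2, 2051, 2100))
  tc <- predict_contacts(touch)
  expect_true(tc$allowed)  # boundary end reaches promoter center: touching
  expect_error(predict_contacts(touch[1, ]), "at least one")
})

test_that("predict_contacts is invariant to feature ordering", {
  toy <- toy_rearranged_locus()
  a <- predict_contacts(toy$features)
  b <- predict_contacts(toy$features[rev(seq_len(nrow(toy$features))), ])
  expect_equal(a, b)
})

test_that("plan summaries report printed-style element sizes", {
  plan <- rearrangement_plan(
    inversion = NULL,
    deletions = parse_genomic_coordinate(c("chr17:85414584–85419213",
                                           "chr17:85743809–85743813")))
  s <- plan_summary(plan)
  expect_equal(s$length_bp, c(4630, 5))
  expect_equal(nrow(plan_summary(rearrangement_plan())), 0)
  # synthetic plan lengths match the bitmap oracle
  p2 <- toy_plan()
  s2 <- plan_summary(p2)
  expect_equal(s2$length_bp[s2$element == "inversion"],
               oracle_coverage_bitmap(p2$inversion))
  expect_equal(sum(s2$length_bp[grepl("deletion", s2$element)]),
               oracle_coverage_bitmap(p2$deletions))
})

test_that("plans and features round-trip through JSON / BED", {
  plan <- toy_plan()
  f <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, f)
  back <- read_plan(f)
  expect_equal(back$inversion$start, plan$inversion$start)
  expect_equal(back$deletions$end, plan$deletions$end)
  expect_equal(back$order, plan$order)
  toy <- toy_rearranged_locus()
  fb <- withr::local_tempfile(fileext = ".bed")
  write_features(toy$features, fb)
  feats <- read_features(fb)
  expect_equal(as.data.frame(feats)[, c("name", "kind", "start", "end")],
               as.data.frame(toy$features)[, c("name", "kind", "start",
                                               "end")])
  fj <- withr::local_tempfile(fileext = ".json")
  write_features(toy$features, fj)
  feats2 <- read_features(fj)
  expect_equal(feats2$start, toy$features$start)
})

test_that("deletions straddling inversion ends are rejected when unsound", {
  expect_error(rearrangement_plan(
    genomic_intervals("chrT", 1000, 2000),
    genomic_intervals("chrT", 950, 1050),
    order = "inversion_first"), "straddle")
  # overlapping deletions rejected outright
  expect_error(rearrangement_plan(
    deletions = genomic_intervals("chrT", c(10, 50), c(60, 100))),
    "disjoint")
})
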