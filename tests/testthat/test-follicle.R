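test_that("staging rules follow the fixed precedence and are total", {
  # exclusion first: no visible nucleus
  r1 <- follicle_record("a", nucleus_visible = FALSE, granulosa_shape = "cuboidal",
                        granulosa_layers = 3)
  expect_equal(classify_follicle(r1), "excluded")
  # flattened single layer, no antrum: primordial
  r2 <- follicle_record("b", granulosa_shape = "flattened", granulosa_layers = 1)
  expect_equal(classify_follicle(r2), "primordial")
  # mixed cuboidal/squamous single layer: primary
  r3 <- follicle_record("c", granulosa_shape = "mixed_cuboidal_squamous",
                        granulosa_layers = 1)
  expect_equal(classify_follicle(r3), "primary")
  # several cuboidal layers: secondary
  r4 <- follicle_record("d", granulosa_shape = "cuboidal", granulosa_layers = 3)
  expect_equal(classify_follicle(r4), "secondary")
  # antrum dominates shape rules
  r5 <- follicle_record("e", granulosa_shape = "cuboidal", granulosa_layers = 6,
                        antrum_present = TRUE)
  expect_equal(classify_follicle(r5), "antral")
  # contradictory: antrum over a flattened single layer -> antral + warning
  r6 <- follicle_record("f", granulosa_shape = "flattened", granulosa_layers = 1,
                        antrum_present = TRUE)
  expect_warning(lab <- classify_follicle(r6), "contradictory")
  expect_equal(lab, "antral")
  # totality over the morphology grid
  shapes <- c("flattened", "mixed_cuboidal_squamous", "cuboidal")
  for (sh in shapes) for (ly in 0:4) for (an in c(FALSE, TRUE)) for (nu in c(FALSE, TRUE)) {
    rec <- follicle_record("x", granulosa_shape = sh, granulosa_layers = ly,
                           antrum_present = an, nucleus_visible = nu)
    lab <- suppressWarnings(classify_follicle(rec))
    expect_true(lab %in% c("primordial", "primary", "secondary", "antral", "excluded"))
  }
})

test_that("stage tallies conserve records and ignore input order", {
  expect_equal(sum(tally_stages(data.frame())$counts), 0)
  co <- gen_follicle_cohort(cohort_spec(n_follicles = 500, seed = 17))
  t1 <- tally_stages(co)
  expect_equal(sum(t1$counts) + t1$excluded, nrow(co))
  # counts equal the generator's truth
  for (st in names(t1$counts)) {
    expect_equal(unname(t1$counts[st]), sum(co$stage == st))
  }
  t2 <- tally_stages(co[sample(nrow(co)), ])
  expect_equal(t2$counts, t1$counts)
})

test_that("MVH/ZP3 count arithmetic and its labelling policies", {
  r <- derive_if_counts(100, 40)
  expect_equal(r$total, 100)
  expect_equal(r$growing, 40)
  expect_equal(r$difference, 60)
  expect_equal(r$difference_label, "primary")       # literal methods wording
  r2 <- derive_if_counts(100, 40, label_policy = "zp3_semantics")
  expect_equal(r2$difference_label, "primordial")   # ZP3-negative = not growing
  expect_equal(derive_if_counts(50, 50)$difference, 0)
  expect_warning(r3 <- derive_if_counts(30, 35), "exceeds")
  expect_equal(r3$difference, 0)
  expect_error(derive_if_counts(-1, 0), ">= 0")
})

make_antral <- function(diams, healthy = TRUE) {
  do.call(rbind, lapply(seq_along(diams), function(i) {
    follicle_record(sprintf("a%d", i), follicle_diameter = diams[i],
                    granulosa_shape = "cuboidal", granulosa_layers = 5,
                    antrum_present = TRUE, healthy = healthy)
  }))
}

test_that("puberty score reproduces the diameter-class table", {
  # largest healthy antral 420 um -> F4, score -1
  expect_equal(puberty_score(make_antral(c(420, 300, 280, 260, 255, 250)))$score, -1)
  # largest 240 um -> SF, score -5
  expect_equal(puberty_score(make_antral(rep(240, 6)))$score, -5)
  # exactly 250 um -> F1 lower bound, score -4
  expect_equal(puberty_score(make_antral(rep(250, 6)))$score, -4)
  # boundary sweep under the half-open convention
  sweep_d <- c(249, 250, 300, 301, 350, 351, 400, 401)
  want <- c("SF", "F1", "F1", "F2", "F2", "F3", "F3", "F4")
  for (i in seq_along(sweep_d)) {
    ps <- suppressWarnings(puberty_score(make_antral(sweep_d[i])))
    expect_equal(ps$top_class, want[i])
  }
})

test_that("puberty score guards, flags, and monotonicity", {
  # unhealthy or non-antral follicles never contribute
  recs <- rbind(make_antral(c(500), healthy = FALSE),
                make_antral(c(260, 270, 280, 290, 300, 310)))
  expect_equal(puberty_score(recs)$six_largest[1], 310)
  # no healthy antral follicles: baseline score with flag
  none <- gen_follicle_cohort(cohort_spec(
    stage_proportions = c(primordial = 1.0),
    diameter_distributions = list(primordial = c(17, 2)),
    n_follicles = 10, seed = 1))
  ps <- puberty_score(none)
  expect_equal(ps$score, -5)
  expect_true("no_antral" %in% ps$flags)
  # fewer than six healthy antral follicles: warned, still scored
  expect_warning(ps2 <- puberty_score(make_antral(c(260, 270))), "fewer than")
  expect_equal(ps2$top_class, "F1")
  # non-positive diameter rejected with ids
  bad <- make_antral(c(300, 310))
  bad$follicle_diameter[1] <- NA
  expect_error(suppressWarnings(puberty_score(bad)), "a1")
  # monotone: growing the largest diameter never lowers the score
  scores <- vapply(seq(100, 500, by = 10), function(d) {
    suppressWarnings(puberty_score(make_antral(d))$score)
  }, integer(1))
  expect_true(all(diff(scores) >= 0))
  expect_true(all(scores >= -5 & scores <= -1))
})
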