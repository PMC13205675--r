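test_that("the bundled synthetic reference loads with all six categories", {
  ref <- load_reference()
  expect_s3_class(ref, "matrisome_reference")
  expect_setequal(unique(ref$entries$category), matrisome_categories()$category)
  expect_equal(nrow(ref$entries), 30)
})

test_that("malformed references are rejected", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("identifier,division,category",
               "col1a1,core matrisome,collagen typo"), bad)
  expect_error(load_reference(bad), "unknown categor")
  writeLines(c("identifier,division,category",
               "col1a1,matrisome-associated,collagens"), bad)
  expect_error(load_reference(bad), "division inconsistent")
  writeLines(c("identifier,division,category",
               "col1a1,core matrisome,collagens",
               "COL1A1,core matrisome,collagens"), bad)
  expect_error(load_reference(bad), "duplicate")
  writeLines("identifier,division,category", bad)
  expect_error(load_reference(bad), "empty")
})

test_that("annotation counts constructed compositions exactly", {
  ref <- load_reference()
  ids <- c("COL1A1", "col1a2", "Col3a1", "col4a1", "col6a1",     # 5 collagens
           "fn1", "lamb1", "thbs4", "tnc", "nid1",
           "FN1", "LAMB1", "THBS4", "TNC", "NID1",               # 10 dup -> 5 glycoproteins
           "novelgene1", "novelgene2", "novelgene3", "novelgene4", "novelgene5")
  res <- annotate_list(ids, ref)
  expect_equal(unname(res$counts["collagens"]), 5)
  expect_equal(unname(res$counts["glycoproteins"]), 5)
  expect_equal(res$non_matrisome, 5)
  expect_equal(res$n_duplicates, 5)
  expect_equal(sum(res$counts) + res$non_matrisome, res$input_size)
  expect_equal(unname(res$percentages["glycoproteins"]), 50)
  # disjoint list: all non-matrisome
  res2 <- annotate_list(c("x1", "x2"), ref)
  expect_equal(sum(res2$counts), 0)
  expect_equal(res2$non_matrisome, 2)
  # identity: the reference's own keys reproduce its composition
  res3 <- annotate_list(ref$entries$identifier, ref)
  expect_equal(unname(res3$counts),
               as.integer(table(ref$entries$category)[names(res3$counts)]))
  expect_equal(sum(res3$percentages), 100, tolerance = 0.1)
})

test_that("Venn regions match the per-element membership-pattern oracle", {
  # three disjoint sets: no intersections
  d <- overlap_sets(list(a = c("x1", "x2"), b = c("y1"), c = c("z1", "z2", "z3")))
  expect_equal(d$regions$count[d$regions$label == "a&b"], 0)
  expect_equal(d$regions$count[d$regions$label == "a&b&c"], 0)
  expect_equal(d$union_size, 6)
  # identical sets: everything in the triple intersection
  s <- sprintf("g%02d", 1:50)
  ident <- overlap_sets(list(h = s, p = s, m = s))
  expect_equal(ident$regions$count[ident$regions$label == "h&p&m"], 50)
  expect_equal(sum(ident$regions$count), 50)
  # random instances vs brute force, conservation of the union
  set.seed(2024)
  for (i in 1:25) {
    ns <- sample(2:4, 1)
    pool <- sprintf("id%03d", 1:80)
    sets <- setNames(lapply(seq_len(ns), function(j) sample(pool, sample(10:60, 1))),
                     letters[seq_len(ns)])
    got <- overlap_sets(sets)
    expect_equal(got$regions$count, venn_oracle(sets))
    expect_equal(sum(got$regions$count), got$union_size)
    expect_equal(nrow(got$membership), got$union_size)
  }
})

test_that("DEG filtering uses strict printed inequalities", {
  tab <- data.frame(identifier = c("a", "b", "c", "d", "e"),
                    log2fc = c(1.0, 1.0001, -1.5, 0.5, -2),
                    p = c(0.01, 0.049, 0.049, 0.001, 0.05))
  out <- deg_filter(tab)
  # |log2fc| = 1.0 exactly is excluded; p = 0.05 exactly is excluded
  expect_setequal(out$subset$identifier, c("b", "c"))
  expect_equal(out$n_up, 1)
  expect_equal(out$n_down, 1)
  # random tables vs brute-force scan
  set.seed(8)
  for (i in 1:20) {
    rt <- data.frame(log2fc = rnorm(200, sd = 1.5), p = runif(200))
    expect_equal(nrow(deg_filter(rt)$subset), length(deg_oracle(rt)))
  }
})

test_that("nine-quadrant states, ordering, and filter consistency", {
  # constructed table hitting each joint state exactly once
  st <- expand.grid(m = c(-2, 0, 2), p = c(-2, 0, 2))
  tab <- data.frame(log2fc_mrna = st$m, p_mrna = ifelse(st$m == 0, 0.5, 0.01),
                    log2fc_protein = st$p, p_protein = ifelse(st$p == 0, 0.5, 0.01))
  qa <- nine_quadrant(tab)
  expect_equal(qa$counts, rep(1L, 9))
  # quadrant 1 is down/down, 5 unchanged/unchanged, 9 up/up
  expect_equal(qa$quadrant[st$m == -2 & st$p == -2], 1L)
  expect_equal(qa$quadrant[st$m == 0 & st$p == 0], 5L)
  expect_equal(qa$quadrant[st$m == 2 & st$p == 2], 9L)
  # everything unchanged when fold changes vanish
  z <- data.frame(log2fc_mrna = rnorm(20, sd = 1e-6), p_mrna = runif(20),
                  log2fc_protein = rnorm(20, sd = 1e-6), p_protein = runif(20))
  expect_equal(nine_quadrant(z)$counts[5], 20L)
  # a non-unchanged axis state implies passing the DEG filter on that axis
  om <- gen_omics_table(omics_table_spec(n_genes = 2000, seed = 6))
  qa2 <- nine_quadrant(om)
  mrna_moved <- qa2$quadrant %in% c(1:3, 7:9)      # mRNA state down or up
  expect_true(all(abs(om$log2fc_mrna[mrna_moved]) > 1 &
                    om$p_mrna[mrna_moved] < 0.05))
  prot_moved <- qa2$quadrant %% 3 != 2             # protein state down (q%%3==1) or up (q%%3==0)
  expect_true(all(abs(om$log2fc_protein[prot_moved]) > 1 &
                    om$p_protein[prot_moved] < 0.05))
  # counts invariant to input order
  perm <- sample(nrow(om))
  expect_equal(nine_quadrant(om[perm, ])$counts, qa2$counts)
})

test_that("Pearson correlation matches hand computation and guards degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x), 1)
  expect_equal(pearson_r(x, -x), -1)
  # fixed 5-point table, hand-computed product-moment value
  y <- c(2, 1, 4, 3, 6)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), num / den, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
})
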