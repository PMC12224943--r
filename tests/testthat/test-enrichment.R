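gene_universe <- function(N) sprintf("g%02d", seq_len(N))

test_that("hypergeometric enrichment matches exact enumeration", {
  bg <- gene_universe(10)
  markers <- bg[1:4]
  cand <- bg[1:5]  # overlap k = 4, n = 5, K = 4, N = 10
  res <- hypergeometric_enrichment(cand, markers, bg)
  expect_equal(res$p_value, 6 / 252)  # C(4,4) C(6,1) / C(10,5)
  expect_equal(res$fold_enrichment, 2)
  expect_equal(res$overlap, 4)

  none <- hypergeometric_enrichment(bg[5:6], bg[1:4], bg)
  expect_equal(none$p_value, 1)

  flagged <- hypergeometric_enrichment(bg[1:3], "absent", bg)
  expect_true(flagged$flagged)
  expect_equal(flagged$p_value, 1)
  expect_equal(flagged$fold_enrichment, 0)
})

test_that("hypergeometric tail agrees with one-sided Fisher on small tables", {
  for (N in c(6, 9, 12)) {
    bg <- gene_universe(N)
    for (K in 1:N) for (n in 1:N) {
      for (k in max(0, K + n - N):min(n, K)) {
        res <- hypergeometric_enrichment(bg[seq_len(n)],
                                         bg[c(seq_len(k),
                                              setdiff(seq_len(N), seq_len(n)))[seq_len(K)]],
                                         bg)
        tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2, 2)
        f <- fisher.test(tab, alternative = "greater")$p.value
        expect_equal(res$p_value, f, tolerance = 1e-12)
      }
    }
  }
})

test_that("p-value adjustment honours explicit family sizes", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bonferroni", 4),
               c(0.04, 0.08, 0.12, 0.16))
  expect_equal(adjust_pvalues(0.3, "bonferroni", 1), 0.3)
  expect_equal(adjust_pvalues(c(0.2, 0.9), "bonferroni", 4), c(0.8, 1))
  expect_error(adjust_pvalues(c(0.1, 0.2), "bonferroni", 1), "family size")
  expect_equal(adjust_pvalues(c(0.01, 0.01), "BH"), c(0.01, 0.01))
  # BH never inverts the raw ordering
  set.seed(6)
  p <- runif(20)
  adj <- adjust_pvalues(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("a candidate-saturated hub is called a key driver", {
  nodes <- gene_universe(50)
  cand <- nodes[1:10]
  hub_edges <- data.frame(regulator = "hub", target = cand)
  chain <- data.frame(regulator = nodes[11:49], target = nodes[12:50])
  net <- regulatory_network(rbind(hub_edges, chain,
                                  data.frame(regulator = nodes[50],
                                             target = "hub")))
  kd <- key_driver_analysis(net, cand)
  hub_row <- kd[kd$node == "hub", ]
  expect_equal(hub_row$overlap, 10)
  expect_equal(hub_row$neighborhood_size, 11)  # 10 targets + 1 regulator
  expect_true(hub_row$is_key_driver)
  # a node with no candidate neighbors cannot be a key driver
  empty <- kd[kd$node == "g20", ]
  expect_false(empty$is_key_driver)
})

test_that("key-driver analysis ignores edge direction", {
  fx <- synth_network_and_sets(80, 15, 2, rng_seed = 3)
  fwd <- key_driver_analysis(fx$network, fx$candidates)
  rev <- key_driver_analysis(igraph::reverse_edges(fx$network),
                             fx$candidates)
  expect_equal(fwd[order(fwd$node), ], rev[order(rev$node), ],
               ignore_attr = TRUE)
})

test_that("disjoint candidates yield an empty KD table with a warning", {
  net <- regulatory_network(data.frame(regulator = "a", target = "b"))
  expect_warning(kd <- key_driver_analysis(net, c("x", "y")), "disjoint")
  expect_equal(nrow(kd), 0)
})

test_that("chi-square edge test uses the expected-edge formula and conserves totals", {
  # 6 KDs, effect A = first 3; wire exactly 10 edges from A-KDs to KDs:
  # 6 to same-effect targets, 4 to other KDs
  kd_any <- sprintf("kd%d", 1:6)
  eff_a <- kd_any[1:3]
  e_same <- data.frame(regulator = rep(eff_a, 2),
                       target = c("kd2", "kd3", "kd1", "kd3", "kd1", "kd2"))
  e_other <- data.frame(regulator = c("kd1", "kd1", "kd2", "kd3"),
                        target = c("kd4", "kd5", "kd6", "kd4"))
  net <- regulatory_network(rbind(e_same, e_other))
  res <- kd_edge_chisquare(net, list(A = eff_a, B = kd_any[4:6]))
  res <- res[res$effect == "A", ]
  expect_equal(res$total_edges_to_kd, 10)
  expect_equal(res$expected_same, 10 * (3 - 1) / (6 - 1))  # = 4
  expect_equal(res$observed_same, 6)
  # expected cells sum to the observed total
  expect_equal(res$expected_same + (res$total_edges_to_kd -
                                      res$expected_same), 10)
  expect_equal(res$statistic, (6 - 4)^2 / 4 + (4 - 6)^2 / 6)
  expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE))
})

test_that("observed equal to expected gives a zero statistic and p = 1", {
  kd_any <- sprintf("kd%d", 1:6)
  eff_a <- kd_any[1:3]
  # expected same-effect = total * 2/5; with 5 edges, expected = 2
  e <- data.frame(regulator = c("kd1", "kd1", "kd2", "kd3", "kd3"),
                  target = c("kd2", "kd3", "kd4", "kd5", "kd6"))
  res <- kd_edge_chisquare(regulatory_network(e),
                           list(A = eff_a, B = kd_any[4:6]))
  res <- res[res$effect == "A", ]
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("relative pathology is a background-corrected ratio", {
  area <- c(treated = 1, control = 1, background = 1)
  expect_equal(relative_pathology(c(treated = 3, control = 5,
                                    background = 1), area), 0.5)
  expect_equal(relative_pathology(c(treated = 5, control = 5,
                                    background = 1), area), 1)
  expect_equal(relative_pathology(c(treated = 1, control = 5,
                                    background = 1), area), 0)
  # invariant to rescaling all densities
  expect_equal(relative_pathology(10 * c(treated = 3, control = 5,
                                         background = 1), area), 0.5)
  expect_warning(
    bad <- relative_pathology(c(treated = 3, control = 1, background = 1),
                              area), "background")
  expect_true(is.na(bad))
})
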