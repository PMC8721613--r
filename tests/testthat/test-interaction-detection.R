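test_that("expected coculture value is the convex mixture of the monocultures", {
  expect_equal(expected_coculture(100, 0, 0.57), 57)
  expect_equal(expected_coculture(10, 10, 0.29), 10)  # convexity fixed point
  expect_equal(expected_coculture(2, 4, 0.57), 2.86)
  expect_error(expected_coculture(1, 1, 1.2), "in \\[0, 1\\]")
  expect_error(expected_coculture(-1, 1, 0.5), ">= 0")
})

test_that("expected value is linear in the monoculture pair and exact at the pi limits", {
  set.seed(31)
  for (i in 1:10) {
    p <- runif(1)
    a <- runif(4, 0, 50)
    expect_equal(expected_coculture(a[1], a[2], p) + expected_coculture(a[3], a[4], p),
                 expected_coculture(a[1] + a[3], a[2] + a[4], p))
    expect_equal(expected_coculture(a[1], a[2], 1), a[1])
    expect_equal(expected_coculture(a[1], a[2], 0), a[2])
  }
})

test_that("fold change divides observed by expected and rejects a zero denominator", {
  expect_equal(fold_change(2, 1), 2)
  expect_equal(fold_change(3.7, 3.7), 1)
  expect_equal(fold_change(expected_coculture(2, 4, 0.57),
                           expected_coculture(2, 4, 0.57)), 1)
  expect_error(fold_change(1, 0), "filter first")
})

test_that("floor filter keeps a trio only when every value is strictly above the floor", {
  expect_false(floor_filter(c(0.2, 5, 5), 0.3))
  expect_true(floor_filter(c(0.31, 0.4, 0.5), 0.3))
  expect_false(floor_filter(c(0.3, 1, 1), 0.3))  # boundary: "above" is strict
  m <- rbind(a = c(1, 1, 1), b = c(1, 0.3, 1))
  expect_identical(floor_filter(m, 0.3), c(a = TRUE, b = FALSE))
})

test_that("raising the floor never increases the number of retained genes", {
  set.seed(32)
  vals <- matrix(rlnorm(300, 0, 2), ncol = 3)
  kept <- vapply(c(0, 0.1, 0.3, 1, 5), function(f) sum(floor_filter(vals, f)),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("gene calls use strict cutoffs and are log-symmetric", {
  expect_identical(classify_gene(2.5), "up")
  expect_identical(classify_gene(2.0), "additive")  # boundary is strict
  expect_identical(classify_gene(0.5), "additive")
  expect_identical(classify_gene(0.4), "down")
  set.seed(33)
  fc <- exp(runif(50, -3, 3))
  flip <- classify_gene(1 / fc)
  calls <- classify_gene(fc)
  expect_identical(calls == "up", flip == "down")
  expect_identical(calls == "down", flip == "up")
  expect_error(classify_gene(1, up_cutoff = 0.5, down_cutoff = 2), "down_cutoff")
})

test_that("detect_pair assigns every gene exactly one call and recovers a planted effect", {
  msc <- c(g1 = 10, g2 = 4, g3 = 8, g4 = 0.1)
  chn <- c(g1 = 6, g2 = 4, g3 = 2, g4 = 5)
  pi <- 0.57
  co <- pi * msc + (1 - pi) * chn
  co["g3"] <- co["g3"] * 3  # planted interaction effect
  mat <- trio_matrix(msc, chn, co)
  res <- detect_pair(mat, tiny_design(), "pA", pi)

  expect_setequal(res$table$call[match(c("g1", "g2", "g3", "g4"), res$table$gene_id)],
                  c("additive", "additive", "up", "filtered"))
  g3 <- res$table[res$table$gene_id == "g3", ]
  expect_equal(g3$fc, 3.0)
  expect_true(all(res$table$fc[res$table$call == "additive"] == 1))
  expect_true(is.na(res$table$fc[res$table$call == "filtered"]))
  expect_equal(sum(res$counts), nrow(mat))  # calls partition the gene set
  # expected value recomputable from the stored monocultures and pi
  keep <- res$table$call != "filtered"
  expect_equal(res$table$co_expected[keep],
               expected_coculture(res$table$msc_mono[keep],
                                  res$table$ch_mono[keep], res$pi))
})

test_that("a trio failing the floor everywhere yields only filtered calls", {
  mat <- trio_matrix(msc = c(g1 = 0.1, g2 = 0.2), ch = c(g1 = 5, g2 = 5),
                     co = c(g1 = 3, g2 = 3))
  res <- detect_pair(mat, tiny_design(), "pA", 0.57)
  expect_identical(unique(res$table$call), "filtered")
  expect_identical(res$counts[["n_filtered"]], 2L)
})

test_that("global floor scope filters on every sample in the matrix", {
  mat <- cbind(trio_matrix(msc = c(g1 = 5), ch = c(g1 = 5), co = c(g1 = 5)),
               other = c(g1 = 0.1))
  d <- tiny_design()
  expect_identical(detect_pair(mat, d, "pA", 0.5)$table$call, "additive")
  expect_identical(detect_pair(mat, d, "pA", 0.5,
                               floor_scope = "global")$table$call, "filtered")
})

test_that("consensus regions match a brute-force set-algebra oracle", {
  set.seed(34)
  genes <- sprintf("g%03d", 1:120)
  for (rep in 1:5) {
    results <- lapply(c("p1", "p2", "p3"), function(pid) {
      call <- sample(c("up", "down", "additive", "filtered"), length(genes),
                     replace = TRUE, prob = c(0.2, 0.2, 0.5, 0.1))
      structure(list(pair_id = pid, pi = 0.57,
                     table = data.frame(gene_id = genes, call = call,
                                        stringsAsFactors = FALSE)),
                class = "additivity_result")
    })
    cons <- consensus(results)
    for (dir in c("up", "down")) {
      sets <- lapply(results, function(r)
        r$table$gene_id[r$table$call == dir])
      names(sets) <- c("p1", "p2", "p3")
      oracle <- brute_force_venn(sets)
      for (key in names(oracle)) {
        expect_identical(sort(cons$region_members[[dir]][[key]]), oracle[[key]])
        got <- cons$regions$n_genes[cons$regions$direction == dir &
                                      cons$regions$region == key]
        expect_identical(got, length(oracle[[key]]))
      }
      # conservation: exclusive regions partition the union of call sets
      expect_identical(
        sum(cons$regions$n_genes[cons$regions$direction == dir]),
        length(Reduce(union, sets)))
      # k-of-n sets are subsets of every constituent per-pair call set
      expect_true(all(cons$k_of_n[[dir]][[3]] %in% sets[[1]]))
      expect_true(all(cons$k_of_n[[dir]][[3]] %in% sets[[3]]))
    }
  }
})

test_that("consensus counts pair-wise membership correctly", {
  mk <- function(pid, calls) structure(
    list(pair_id = pid, pi = 0.57,
         table = data.frame(gene_id = names(calls), call = unname(calls),
                            stringsAsFactors = FALSE)),
    class = "additivity_result")
  res <- list(mk("a", c(g1 = "up", g2 = "up")),
              mk("b", c(g1 = "up", g2 = "up")),
              mk("c", c(g1 = "up", g2 = "additive")))
  cons <- consensus(res)
  expect_identical(cons$k_of_n$up[[3]], "g1")             # up in all three
  expect_identical(cons$region_members$up[["a&b"]], "g2")  # exactly-2 region
  expect_identical(cons$genes$up_count, c(3, 2))
  expect_error(consensus(res[1]), ">= 2 pairs")
  res[[2]]$table$gene_id <- c("g1", "gX")
  expect_error(consensus(res), "mismatched gene universes")
})

test_that("bootstrap deviation p-values behave at the null, under strong deviation, and deterministically", {
  # fc = 1: no deviation, maximal p
  expect_equal(deviation_pvalue(10, 10, 10, 0.57, sigma = 0.1), 1)
  # fc = 8 against sigma = 0.05 noise: tail probability below 0.01
  # (Monte-Carlo oracle: |log 8| = 2.08 vs null sd sqrt(3)*0.05)
  p <- deviation_pvalue(10, 10, 80, 0.57, sigma = 0.05, n_resamples = 999,
                        seed = 5)
  expect_lte(p, 0.01)
  # identical seeds give identical p
  p2 <- deviation_pvalue(10, 5, 30, 0.57, sigma = 0.2, seed = 7)
  p3 <- deviation_pvalue(10, 5, 30, 0.57, sigma = 0.2, seed = 7)
  expect_identical(p2, p3)
  # sigma = 0 with a real deviation: add-one floor with a warning
  expect_warning(p0 <- deviation_pvalue(10, 10, 20, 0.57, sigma = 0,
                                        n_resamples = 199), "add-one floor")
  expect_equal(p0, 1 / 200)
  expect_error(deviation_pvalue(1, 1, 1, 0.5, 0.1, n_resamples = 10), ">= 100")
})
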