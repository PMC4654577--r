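comp_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- c("A", "B", "C")
  m
}

test_that("component ranking is dense with ties sharing the better rank", {
  expect_equal(unname(rank_components(c(300, 200, 100))), c(1L, 2L, 3L))
  expect_equal(unname(rank_components(c(200, 200, 100))), c(1L, 1L, 3L))
  expect_equal(unname(rank_components(c(100, 200, 200))), c(3L, 1L, 1L))
  expect_equal(unname(rank_components(c(5, 5, 5))), c(1L, 1L, 1L))
  expect_equal(unname(rank_components(c(1, 2, 3), higher_better = FALSE)),
               c(1L, 2L, 3L))
})

test_that("pairwise comparison needs at least four of seven components", {
  m7 <- comp_matrix(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3),
                    c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(pairwise_compare(m7, "A", "B"), "a_over_b")
  expect_equal(pairwise_compare(m7, "B", "A"), "b_over_a")

  # a better on 4, b better on 3: meets "at least four"
  m43 <- comp_matrix(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3),
                     c(2, 1, 3), c(2, 1, 3), c(2, 1, 3))
  expect_equal(pairwise_compare(m43, "A", "B"), "a_over_b")
  # ... but not under the strict no-reversals reading
  expect_equal(pairwise_compare(m43, "A", "B", strict = TRUE), "tie")

  # a better on 3, ties on 4: tie
  m3t <- comp_matrix(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 1, 3),
                     c(1, 1, 3), c(2, 2, 3), c(2, 2, 3))
  expect_equal(pairwise_compare(m3t, "A", "B"), "tie")

  expect_error(pairwise_compare(m7, "A", "A"), "itself")
})

test_that("aggregation reproduces the observed hierarchy patterns", {
  all123 <- comp_matrix(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3),
                        c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  agg <- aggregate_ranks(all123)
  expect_equal(unname(agg$ranks), c(1, 2, 3))
  expect_equal(agg$hierarchy_class, "transitive")

  # A and B split evenly, both over C: top tie at 1.5
  split_ab <- comp_matrix(c(1, 2, 3), c(2, 1, 3), c(1, 2, 3), c(2, 1, 3),
                          c(1, 2, 3), c(2, 1, 3), c(1, 1, 3))
  agg2 <- aggregate_ranks(split_ab)
  expect_equal(unname(agg2$ranks), c(1.5, 1.5, 3))
  expect_equal(agg2$hierarchy_class, "top_tie")

  # bottom pair undifferentiated: 2.5s
  split_bc <- comp_matrix(c(1, 2, 3), c(1, 3, 2), c(1, 2, 3), c(1, 3, 2),
                          c(1, 2, 3), c(1, 3, 2), c(1, 2, 2))
  agg3 <- aggregate_ranks(split_bc)
  expect_equal(unname(agg3$ranks), c(1, 2.5, 2.5))
  expect_equal(agg3$hierarchy_class, "bottom_tie")

  flat <- comp_matrix(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3), c(3, 2, 1),
                      c(1, 2, 3), c(3, 2, 1), c(1, 1, 1))
  agg4 <- aggregate_ranks(flat)
  expect_equal(unname(agg4$ranks), c(2, 2, 2))
  expect_equal(agg4$hierarchy_class, "flat")
})

test_that("aggregation agrees with exhaustive rule evaluation on 2-component grids", {
  # all valid 3-member rank vectors under the shared-better-rank convention
  vecs <- unique(c(
    lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)), identity),
    lapply(list(c(1,1,3), c(1,3,1), c(3,1,1), c(1,2,2), c(2,1,2), c(2,2,1),
                c(1,1,1)), identity)))
  oracle_pair <- function(m, i, j) {
    need <- ceiling(4 / 7 * nrow(m)) # 2 of 2 components here
    wins_i <- sum(m[, i] < m[, j])
    wins_j <- sum(m[, j] < m[, i])
    if (wins_i >= need) "i" else if (wins_j >= need) "j" else "tie"
  }
  oracle_ranks <- function(m) {
    r <- c(A = 1, B = 1, C = 1)
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      o <- oracle_pair(m, p[1], p[2])
      if (o == "i") r[p[2]] <- r[p[2]] + 1
      else if (o == "j") r[p[1]] <- r[p[1]] + 1
      else r[p] <- r[p] + 0.5
    }
    r
  }
  for (v1 in vecs) for (v2 in vecs) {
    m <- comp_matrix(v1, v2)
    agg <- aggregate_ranks(m)
    expect_equal(sum(agg$ranks), 6)
    if (agg$hierarchy_class != "unresolved") {
      expect_equal(agg$ranks, oracle_ranks(m))
    }
  }
})

test_that("aggregation is equivariant under member relabeling and sums to 6", {
  set.seed(13)
  for (i in 1:40) {
    m <- comp_matrix(sample(1:3), sample(1:3), sample(1:3), sample(1:3),
                     rank_components(rnorm(3)), rank_components(rnorm(3)),
                     rank_components(rnorm(3)))
    agg <- aggregate_ranks(m)
    expect_equal(sum(agg$ranks), 6)
    perm <- sample(3)
    m2 <- m[, perm]
    agg2 <- aggregate_ranks(m2)
    expect_equal(agg2$ranks, agg$ranks[perm])
    expect_equal(agg2$hierarchy_class, agg$hierarchy_class)
  }
})

test_that("zero-noise synthetic components reproduce the latent order, with ties", {
  comp <- synth_status_components(c(A = 1, B = 2, C = 3), judge_noise = 0,
                                  seed = 1)
  wide <- tidyr::pivot_wider(comp, names_from = "subject_id", values_from = "rank")
  m <- as.matrix(wide[, c("A", "B", "C")])
  expect_true(all(m == rep(c(1, 2, 3), each = 7)))
  expect_equal(unname(aggregate_ranks(m)$ranks), c(1, 2, 3))

  tied <- synth_status_components(c(A = 1.5, B = 1.5, C = 3), judge_noise = 0,
                                  seed = 2)
  widet <- tidyr::pivot_wider(tied, names_from = "subject_id", values_from = "rank")
  mt <- as.matrix(widet[, c("A", "B", "C")])
  aggt <- aggregate_ranks(mt)
  expect_equal(unname(aggt$ranks), c(1.5, 1.5, 3))
  expect_equal(aggt$hierarchy_class, "top_tie")
})

test_that("judge noise increases tie frequency", {
  tie_freq <- function(noise, n = 300, seed = 3) {
    set.seed(seed)
    ties <- 0
    for (i in seq_len(n)) {
      comp <- synth_status_components(stats::setNames(sample(1:3), c("A", "B", "C")),
                                      judge_noise = noise)
      wide <- tidyr::pivot_wider(comp, names_from = "subject_id",
                                 values_from = "rank")
      m <- as.matrix(wide[, c("A", "B", "C")])
      ties <- ties + sum(duplicated(aggregate_ranks(m)$ranks))
    }
    ties / n
  }
  expect_gt(tie_freq(1.5), tie_freq(0))
})

test_that("tie tally counts three pairs per triad", {
  ranks <- tibble::tibble(
    triad_id = rep(c("t1", "t2", "t3"), each = 3),
    subject_id = paste0("s", 1:9),
    final_rank = c(1, 2, 3, 1.5, 1.5, 3, 2, 2, 2))
  tt <- tally_ties(ranks)
  expect_equal(tt$n_pairs, 9L)
  expect_equal(tt$n_ties, 4L) # 0 + 1 + 3
  expect_equal(tally_ties(ranks[0, ])$n_ties, 0L)
  # fifteen triads give 45 possible pairings
  r15 <- tibble::tibble(triad_id = rep(sprintf("t%02d", 1:15), each = 3),
                        subject_id = paste0("s", 1:45),
                        final_rank = rep(c(1, 2, 3), 15))
  expect_equal(tally_ties(r15)$n_pairs, 45L)
  r_flat <- dplyr::mutate(r15, final_rank = 2)
  expect_equal(tally_ties(r_flat)$n_ties, 45L)
})
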