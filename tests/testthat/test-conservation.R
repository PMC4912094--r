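test_that("homology filter applies all four criteria with correct boundaries", {
  expect_false(filter_homologous_pair(100, 160, 0.8, 0.5, 0, 0))  # 160 > 150
  expect_true(filter_homologous_pair(100, 150, 0.8, 0.5, 0, 0))   # 150 allowed
  expect_false(filter_homologous_pair(100, 100, 0.5, 0.5, 0, 0))  # TM strict
  expect_true(filter_homologous_pair(100, 100, 0.51, 0.10, 4, 4)) # all at bound
  expect_false(filter_homologous_pair(100, 100, 0.8, 0.09, 0, 0))
  expect_false(filter_homologous_pair(100, 100, 0.8, 0.5, 5, 0))
  expect_true(filter_homologous_pair(100, 100, 1.0, 1.0, 0, 0))   # identical
})

test_that("the pair's most disrupted site follows the windowed-max rule", {
  mkprof <- function(cols, thetas, eps = 5) {
    tibble::tibble(helix_id = "h", site_index = seq_along(cols) - 1L,
                   auth_res = as.character(seq_along(cols)),
                   theta_deg = thetas, r_n = 0.3, r_c = 0.3,
                   epsilon_deg = eps, column = as.integer(cols))
  }
  # identical profiles: theta_max = theta_min at the same column
  a <- mkprof(5:9, c(5, 10, 35, 8, 4))
  md <- pair_most_disrupted(a, a)
  expect_false(md$removed)
  expect_equal(md$col_max, md$col_min)
  expect_equal(md$theta_max, md$theta_min)
  # windowed maximum of the partner helix
  b <- mkprof(c(7, 13, 20), c(12, 18, 25))
  a2 <- mkprof(10, 35)
  md2 <- pair_most_disrupted(a2, b)
  expect_equal(md2$theta_max, 35)
  expect_equal(md2$theta_min, 18)   # max over columns 6..14
  expect_equal(md2$col_min, 13L)
  # partner gapped across the whole window -> removed
  c2 <- mkprof(c(20, 25), c(12, 14))
  md3 <- pair_most_disrupted(a2, c2)
  expect_true(md3$removed)
})

test_that("pair classification matches the rules, partitions, and is swap-symmetric", {
  expect_equal(classify_pair(15, 3, 5, 5), "ConservedStraight")
  expect_equal(classify_pair(30, 25, 4, 5), "ConservedKinked")
  expect_equal(classify_pair(30, 20, 4, 5), "NotConserved")    # 10 > 9
  expect_equal(classify_pair(25, 15, 6, 6), "Other")           # 10 <= 12, min <= 20
  # exhaustive truth-table over a grid, against an independent re-statement
  grid <- expand.grid(theta_max = c(5, 15, 19.9, 20, 20.1, 25, 40, 60),
                      theta_min = c(0, 5, 15, 19.9, 20, 20.1, 25, 40),
                      eps_sum = c(0, 1, 5, 9, 15, 30))
  grid <- grid[grid$theta_max >= grid$theta_min, ]
  got <- classify_pair(grid$theta_max, grid$theta_min,
                       grid$eps_sum / 2, grid$eps_sum / 2)
  oracle <- apply(grid, 1, function(g) {
    if (g["theta_max"] < 20) return("ConservedStraight")
    sig <- (g["theta_max"] - g["theta_min"]) > g["eps_sum"]
    if (g["theta_min"] > 20 && !sig) return("ConservedKinked")
    if (g["theta_max"] > 20 && sig) return("NotConserved")
    "Other"
  })
  expect_equal(got, unname(oracle))
  expect_true(all(got %in% c("ConservedStraight", "ConservedKinked",
                             "NotConserved", "Other")))
  # shrinking both errors to zero never moves a pair from NC towards CK
  got0 <- classify_pair(grid$theta_max, grid$theta_min, 0, 0)
  expect_false(any(got == "NotConserved" & got0 == "ConservedKinked"))
})

test_that("three-column max smoothing matches its brute-force definition", {
  x <- tibble::tibble(column = 0:3, theta_deg = c(10, 30, 12, 5),
                      epsilon_deg = c(1, 2, 3, 4))
  s <- smooth_profile(x)
  expect_equal(s$theta_smoothed[s$column %in% 0:3], c(30, 30, 30, 12))
  expect_equal(s$epsilon_deg[s$column == 1], 2)   # epsilon of the winner
  # constant profile unchanged
  const <- tibble::tibble(column = 0:4, theta_deg = 7, epsilon_deg = 1)
  expect_true(all(smooth_profile(const)$theta_smoothed == 7))
  # an isolated angle spreads to exactly its three-window columns
  iso <- tibble::tibble(column = 10L, theta_deg = 22, epsilon_deg = 1)
  s2 <- smooth_profile(iso)
  expect_equal(s2$column, 9:11)
  expect_true(all(s2$theta_smoothed == 22))
  # smoothing never decreases any defined value (random fixture)
  set.seed(8)
  for (i in 1:20) {
    cols <- sort(sample(0:30, 12))
    rnd <- tibble::tibble(column = cols, theta_deg = runif(12, 0, 60),
                          epsilon_deg = 5)
    sm <- smooth_profile(rnd)
    joined <- merge(rnd, sm, by = "column")
    expect_true(all(joined$theta_smoothed >= joined$theta_deg))
    # brute-force oracle at every output column
    for (k in seq_len(nrow(sm))) {
      inwin <- rnd$theta_deg[abs(rnd$column - sm$column[k]) <= 1]
      expect_equal(sm$theta_smoothed[k], max(inwin))
    }
  }
})

test_that("the family's most disrupted site needs >= 5 angles and takes the best mean", {
  mkfam <- function(df) df
  # identical kinked members: the kink column wins
  fam <- dplyr::bind_rows(lapply(1:6, function(m) {
    tibble::tibble(member = paste0("m", m), column = 0:8,
                   theta_deg = c(2, 3, 2, 4, 45, 4, 3, 2, 2), epsilon_deg = 5)
  }))
  sm <- smooth_family(fam)
  # max-smoothing spreads the kink value over columns 3..5 with equal means;
  # the deterministic tie rule picks the smallest, one left of the kink
  expect_equal(family_most_disrupted(sm), 3L)
  expect_equal(classify_family(sm)$theta_median, 45)
  # a 4-angle column with mean 50 loses to a 6-angle column with mean 30
  sparse <- dplyr::bind_rows(
    lapply(1:4, function(m) tibble::tibble(member = paste0("a", m),
                                           column = 100L, theta_smoothed = 50,
                                           epsilon_deg = 5)),
    lapply(1:6, function(m) tibble::tibble(member = paste0("b", m),
                                           column = 200L, theta_smoothed = 30,
                                           epsilon_deg = 5)))
  expect_equal(family_most_disrupted(sparse), 200L)
  # random families agree with a brute-force scan
  set.seed(17)
  for (i in 1:10) {
    rnd <- dplyr::bind_rows(lapply(1:7, function(m) {
      cols <- sort(sample(0:12, 9))
      tibble::tibble(member = paste0("m", m), column = cols,
                     theta_deg = runif(9, 0, 50), epsilon_deg = 5)
    }))
    smr <- smooth_family(rnd)
    got <- family_most_disrupted(smr)
    per_col <- aggregate(theta_smoothed ~ column, smr, mean)
    per_col$n <- aggregate(theta_smoothed ~ column, smr, length)$theta_smoothed
    elig <- per_col[per_col$n >= 5, ]
    best <- elig$column[order(-elig$theta_smoothed, elig$column)][1]
    expect_equal(got, as.integer(best))
  }
})

test_that("family classification compares angle spread to mean error", {
  at_col <- function(thetas, eps) {
    dplyr::bind_rows(lapply(seq_along(thetas), function(i) {
      tibble::tibble(member = paste0("m", i), column = 0L,
                     theta_smoothed = thetas[i], epsilon_deg = eps)
    }))
  }
  ck <- classify_family(at_col(c(39, 40, 41, 40, 39.5, 40.5), 8), column = 0L)
  expect_equal(ck$class, "ConservedKinked")
  nc <- classify_family(at_col(c(5, 10, 40, 45, 50), 7), column = 0L)
  expect_equal(nc$class, "NotConserved")
  expect_equal(nc$sigma_theta, 20.9165, tolerance = 1e-4)  # n-1 denominator
  cs <- classify_family(at_col(c(10, 12, 11, 13, 12), 7), column = 0L)
  expect_equal(cs$class, "ConservedStraight")
  # sigma > mu_eps but everything under 20 degrees -> Other
  ot <- classify_family(at_col(c(1, 5, 9, 14, 19), 2), column = 0L)
  expect_equal(ot$class, "Other")
  expect_error(classify_family(at_col(c(1, 2, 3, 4), 2), column = 0L), "fewer than")
})

test_that("family pruning removes low-connectivity members deterministically", {
  # complete graph on 6 nodes: everyone retained
  nodes <- paste0("n", 1:6)
  full <- t(utils::combn(nodes, 2))
  expect_equal(prune_family(nodes, as.data.frame(full)), sort(nodes))
  # one node connected to only 3 of 5 others is removed; 5 remain
  partial <- full[!(full[, 1] == "n6" & full[, 2] %in% c("n1", "n2")) &
                    !(full[, 2] == "n6" & full[, 1] %in% c("n1", "n2")), ]
  kept <- prune_family(nodes, as.data.frame(partial))
  expect_equal(kept, paste0("n", 1:5))
  # result independent of member order
  expect_equal(prune_family(rev(nodes), as.data.frame(partial)), kept)
  # communities reduced below five members are discarded
  small <- data.frame(a = c("x1", "x2"), b = c("x2", "x3"))
  expect_equal(prune_family(c("x1", "x2", "x3"), small), character(0))
})

test_that("sequence identity ignores gap columns; families average pairs", {
  expect_equal(sequence_identity("ACDEF", "ACD-F"), 1.0)
  expect_equal(sequence_identity("ACDEF", "ACDEF"), 1.0)
  expect_equal(sequence_identity("AAAA", "AATT"), 0.5)
  expect_true(is.na(sequence_identity("--", "AA")))
  expect_equal(sequence_identity("APKL", "AQKL", columns = c(0L, 1L)), 0.5)
  # pairwise identities {1, 0.5, 0.5} -> family mean 2/3
  expect_equal(family_sequence_identity(c("AC", "AC", "AG")), 2 / 3)
  expect_error(family_sequence_identity("AC"), "two sequences")
})

test_that("neighbouring sequence identity counts 4 A contacts, not gaps", {
  model_a <- make_contact_fixture()
  model_b <- model_a
  # chain sequences: 12 helix residues + 6 contacts + 3 far, ungapped
  seq_a <- paste(rep("A", 21), collapse = "")
  # mutate one contacting residue (position 14, 1-based) in the partner
  chars <- strsplit(seq_a, "")[[1]]; chars[14] <- "W"
  seq_b <- paste(chars, collapse = "")
  res <- neighbouring_sequence_identity(model_a, model_b,
                                        "A", c(1L, 12L), seq_a,
                                        "A", c(1L, 12L), seq_b)
  expect_equal(res$n_neighbours_a, 6L)
  expect_equal(sort(res$columns), 12:17)   # 0-based columns of residues 13-18
  expect_equal(res$identity, 5 / 6)
  # identical structures and sequences: identity 1
  same <- neighbouring_sequence_identity(model_a, model_a,
                                         "A", c(1L, 12L), seq_a,
                                         "A", c(1L, 12L), seq_a)
  expect_equal(same$identity, 1.0)
  # no residue within 4 A -> missing value, not zero
  far_only <- model_a[!(model_a$resno %in% 13:18), ]
  class(far_only) <- class(model_a)
  seq_short <- paste(rep("A", 15), collapse = "")
  none <- neighbouring_sequence_identity(far_only, far_only,
                                         "A", c(1L, 12L), seq_short,
                                         "A", c(1L, 12L), seq_short)
  expect_true(is.na(none$identity))
})

test_that("site-site Spearman correlation uses average ranks and needs 5 members", {
  mk2 <- function(ti, tj) {
    dplyr::bind_rows(lapply(seq_along(ti), function(m) {
      tibble::tibble(member = paste0("m", m),
                     column = c(1L, 2L),
                     theta_smoothed = c(ti[m], tj[m]))
    }))
  }
  mono <- mk2(c(1, 2, 3, 4, 5, 6), c(10, 20, 30, 40, 50, 60))
  expect_equal(correlate_sites(mono, 1L, 2L), 1.0)
  anti <- mk2(c(1, 2, 3, 4, 5, 6), c(60, 50, 40, 30, 20, 10))
  expect_equal(correlate_sites(anti, 1L, 2L), -1.0)
  # fixed 6-pair table against the hand rank formula (no ties)
  ti <- c(12, 45, 23, 38, 5, 30); tj <- c(14, 40, 30, 26, 8, 22)
  d <- rank(ti) - rank(tj)
  rho_hand <- 1 - 6 * sum(d^2) / (6 * (36 - 1))
  expect_equal(correlate_sites(mk2(ti, tj), 1L, 2L), rho_hand)
  expect_error(correlate_sites(mk2(1:4, 1:4), 1L, 2L), "fewer than 5")
})

test_that("aligned families classify end to end from synthetic fixtures", {
  dir <- withr::local_tempdir()
  run_family <- function(angles, sub) {
    fam <- generate_family_fixture(angles, file.path(dir, sub), seed = 5)
    ann <- read_helix_annotations(attr(fam, "annotations"))
    aln <- read_alignment(attr(fam, "alignment"))
    profiles <- lapply(seq_len(nrow(fam)), function(i) {
      m <- read_structure(fam$pdb[i])
      measure_angles(extract_helix(m, ann$chain[i], ann$start_res[i],
                                   ann$end_res[i], helix_id = fam$member[i]))
    })
    names(profiles) <- fam$member
    sm <- smooth_family(family_angles(profiles, aln))
    classify_family(sm)
  }
  expect_equal(run_family(rep(40, 6), "ck")$class, "ConservedKinked")
  expect_equal(run_family(c(0, 0, 5, 35, 40, 45), "nc")$class, "NotConserved")
  expect_equal(run_family(rep(0, 5), "cs")$class, "ConservedStraight")
})

test_that("pair pipeline classifies and flags proline from the alignment", {
  a <- measure_angles(generate_kinked_helix(20, 35, 10, helix_id = "a"))
  b <- measure_angles(generate_kinked_helix(20, 33, 10, helix_id = "b"))
  seq_a <- paste(rep("A", 20), collapse = "")
  chars <- strsplit(seq_a, "")[[1]]; chars[12] <- "P"  # 2 after the kink site
  seq_p <- paste(chars, collapse = "")
  res <- classify_helix_pair(a, b, seq_p, seq_a)
  expect_equal(res$class, "ConservedKinked")
  expect_true(res$proline_max || res$proline_min)   # proline in helix a only
  expect_equal(sum(c(res$proline_max, res$proline_min)), 1L)
  # gaps that push the partner's angles out of the window remove the pair
  row_a <- paste(c(rep("A", 20), rep("-", 10)), collapse = "")
  row_b <- paste(c(rep("-", 10), rep("A", 20)), collapse = "")
  removed <- classify_helix_pair(a, b, row_a, row_b)
  expect_equal(removed$class, "Removed")
  # a profile longer than its alignment row is rejected
  expect_error(aligned_profile(a, "AAAA"), "residues")
})
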