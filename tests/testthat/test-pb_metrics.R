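test_that("frequencies count letters over non-Z frames only", {
  m <- matrix("d", 10, 3)
  pb <- pb_ensemble(m, 1:3)
  p <- pb_frequencies(pb)
  expect_equal(unname(p$freq[, "d"]), rep(1, 3))
  expect_equal(rowSums(p$freq), c(`1` = 1, `2` = 1, `3` = 1))

  mixed <- pb_ensemble(matrix(c("d", "d", "h", "Z"), 4, 1), 5)
  pm <- pb_frequencies(mixed)
  expect_equal(unname(pm$freq[1, "d"]), 2 / 3)
  expect_equal(unname(pm$freq[1, "h"]), 1 / 3)
  expect_equal(pm$n, 3L)
  expect_true(pm$low_confidence)

  allz <- pb_ensemble(matrix("Z", 4, 1), 9)
  expect_true(pb_frequencies(allz)$empty)
  expect_true(all(is.na(pb_frequencies(allz)$freq)))
})

test_that("string-mode sampling recovers target frequencies at 10k frames", {
  tgt <- c(b = 0.6, d = 0.2, h = 0.2)
  sp <- generator_spec(1:5, tgt, n_frames = 10000, n_replicates = 1,
                       seed = 42)
  p <- pb_frequencies(generate_string_mode(sp))
  expect_true(all(abs(p$freq[, "b"] - 0.6) < 0.02))
  expect_true(all(abs(p$freq[, "d"] - 0.2) < 0.02))
  expect_true(all(abs(p$freq[, "h"] - 0.2) < 0.02))
  expect_true(all(p$freq[, setdiff(colnames(p$freq), c("b", "d", "h"))] == 0))
})

test_that("Neq hits its analytic limits and worked values", {
  expect_equal(neq(c(1, rep(0, 15))), 1)
  expect_equal(neq(rep(1 / 16, 16)), 16, tolerance = 1e-12)
  # three-letter mixture: exp(0.6 ln(1/0.6) + 0.4 ln 5)
  f <- pb_target(c(b = 0.6, d = 0.2, h = 0.2))
  expect_equal(neq(f), exp(0.6 * log(1 / 0.6) + 0.4 * log(5)),
               tolerance = 1e-12)
  expect_equal(neq(f), 2.5863, tolerance = 1e-4)
  expect_error(neq(c(0.9, rep(0, 15))), "sums to")
  expect_error(neq(c(-0.1, 1.1, rep(0, 14))), "negative")
})

test_that("Neq equals the independent entropy oracle on random rows", {
  set.seed(10)
  for (i in 1:1000) {
    f <- random_pb_row()
    expect_equal(neq(f), oracle_neq(f), tolerance = 1e-12)
  }
  # matrix form agrees with row-wise evaluation
  m <- t(replicate(20, random_pb_row()))
  expect_equal(unname(neq(m)), apply(m, 1, oracle_neq), tolerance = 1e-12)
})

test_that("flexibility classes follow the Neq thresholds", {
  expect_equal(as.character(classify_flexibility(c(9, 7, 1, 4, 2.9))),
               c("disordered", "highly_flexible", "rigid", "flexible",
                 "rigid"))
  expect_equal(as.character(classify_flexibility(c(8, 6, 3))),
               c("highly_flexible", "flexible", "flexible"))
  expect_error(classify_flexibility(17), "out of")
  expect_error(classify_flexibility(0.5), "out of")
})

test_that("dNeq is the absolute difference on shared positions", {
  a <- structure(data.frame(resno = 1:3, neq = c(2.5, 1, 4)),
                 class = c("flex_profile", "data.frame"))
  b <- structure(data.frame(resno = 2:4, neq = c(1, 1.5, 2)),
                 class = c("flex_profile", "data.frame"))
  d <- delta_neq(a, b)
  expect_equal(d$resno, 2:3)
  expect_equal(d$dneq, c(0, 2.5))
  expect_equal(delta_neq(a, a)$dneq, rep(0, 3))
  expect_error(delta_neq(a, structure(data.frame(resno = 9, neq = 1),
                                      class = class(a))), "no residue")
})

test_that("dPB spans [0, 2] with the printed residue-796 worked example", {
  f <- random_pb_row()
  expect_equal(delta_pb(f, f)$dpb, 0)
  expect_equal(delta_pb(pb_target(c(d = 1)), pb_target(c(h = 1)))$dpb, 2)
  r796 <- delta_pb(pb_target(c(b = 0.6, d = 0.2, h = 0.2)),
                   pb_target(c(h = 1)))
  expect_equal(r796$dpb, 1.6, tolerance = 1e-12)
  expect_equal(unname(r796$per_letter["h"]), 0.8, tolerance = 1e-12)
  expect_error(delta_pb(f, f * 0.5), "normalised")
})

test_that("dPB is a symmetric bounded metric on random profile pairs", {
  set.seed(12)
  for (i in 1:200) {
    a <- random_pb_row(); b <- random_pb_row(); cc <- random_pb_row()
    ab <- delta_pb(a, b)$dpb
    expect_equal(ab, delta_pb(b, a)$dpb, tolerance = 1e-12)
    expect_gte(ab, 0)
    expect_lte(ab, 2)
    expect_lte(ab, delta_pb(a, cc)$dpb + delta_pb(cc, b)$dpb + 1e-12)
  }
})

test_that("consensus-letter frames never increase Neq", {
  set.seed(13)
  for (i in 1:25) {
    lets <- sample(letters[1:16], 30, replace = TRUE, prob = random_pb_row())
    consensus <- names(which.max(table(lets)))
    n0 <- neq(pb_frequencies(pb_ensemble(matrix(lets, ncol = 1), 1))$freq)
    n1 <- neq(pb_frequencies(pb_ensemble(
      matrix(c(lets, rep(consensus, 10)), ncol = 1), 1))$freq)
    expect_lte(n1, n0 + 1e-12)
  }
})

test_that("occurrence maps are profile sub-matrices with unit rows", {
  sp <- generator_spec(101:110, c(b = 0.6, d = 0.2, h = 0.2), n_frames = 200,
                       n_replicates = 1, seed = 3)
  p <- pb_frequencies(generate_string_mode(sp))
  whole <- occurrence_map(p, c(101, 110))
  expect_equal(dim(whole), c(10, 16))
  expect_equal(unname(rowSums(whole)), rep(1, 10))
  sub <- occurrence_map(p, c(104, 106))
  expect_equal(sub, p$freq[as.character(104:106), ])
  one <- pb_frequencies(pb_ensemble(matrix("d", 5, 1), 7))
  m1 <- occurrence_map(one, c(7, 7))
  expect_equal(unname(m1[1, "d"]), 1)
  expect_error(occurrence_map(p, c(900, 950)), "outside")
})

test_that("logo heights are frequencies sorted tallest-first", {
  pb <- pb_ensemble(matrix(c(rep("b", 6), rep("d", 2), rep("h", 2)),
                           ncol = 1), 796)
  lt <- logo_table(pb_frequencies(pb), c(796, 796))
  expect_equal(lt$letter, c("b", "d", "h"))
  expect_equal(lt$height, c(0.6, 0.2, 0.2))
  expect_equal(lt$rank, 1:3)
  expect_equal(sum(lt$height), 1)
  pure <- pb_frequencies(pb_ensemble(matrix("d", 3, 1), 5))
  lp <- logo_table(pure, c(5, 5))
  expect_equal(lp$letter, "d")
  expect_equal(lp$height, 1)
  # empty positions are omitted with a note
  mix <- pb_ensemble(cbind(rep("d", 3), rep("Z", 3)), 5:6)
  expect_message(lt2 <- logo_table(pb_frequencies(mix), c(5, 6)), "omitting")
  expect_equal(unique(lt2$resno), 5)
})

test_that("replicate profiles are near-identical for iid replicates", {
  sp <- generator_spec(1:20, c(b = 0.4, d = 0.3, h = 0.2, m = 0.1),
                       n_frames = 400, n_replicates = 3, seed = 5)
  pb <- generate_string_mode(sp)
  rp <- replicate_profiles(pb, attr(pb, "replicate"))
  expect_equal(length(rp$profiles), 3)
  expect_equal(nrow(rp$neq_correlations), 3)
  # iid replicates from one target: Neq tracks are flat up to noise, so the
  # per-replicate frequency estimates should agree closely instead
  for (r in 2:3) {
    expect_lt(max(abs(rp$profiles[[1]]$freq - rp$profiles[[r]]$freq)), 0.12)
  }
})

test_that("track TSVs are byte-stable across writes", {
  tr <- data.frame(resno = 1:3, neq = c(1.234567891, 2, 3.5))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_track_tsv(tr, f1)
  write_track_tsv(tr, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[2], "1\t1.234568")
})
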