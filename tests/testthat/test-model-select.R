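make_ca <- function(n_templates, seed = 11, k = NULL) {
  tm <- generate_template_set(max(n_templates, 2), length = 40, seed = seed)
  tgt <- flag_hars(mutate_sequence(tm[[1]]$seq, sub_rate = 0.2, seed = seed))
  alns <- align_all(tgt, tm)
  list(target = tgt, templates = tm,
       ca = suppressWarnings(
         select_candidates(alns, k = if (is.null(k)) n_templates else k)))
}

test_that("enumeration yields singles first, then unique unordered pairs", {
  x <- make_ca(4)
  cands <- enumerate_candidates(x$ca, x$templates)
  n <- length(x$ca$members)
  expect_length(cands, n + choose(n, 2))
  origin <- unname(vapply(cands, `[[`, "", "origin"))
  expect_equal(origin, c(rep("single", n), rep("double", choose(n, 2))))
  ids <- vapply(cands, `[[`, "", "candidate_id")
  expect_equal(anyDuplicated(ids), 0L)
  # no self-pairs
  dbl <- cands[origin == "double"]
  expect_true(all(vapply(dbl, function(c)
    c$template_ids[1] != c$template_ids[2], TRUE)))
})

test_that("the mock scorer hits its optimum on a perfect self-match", {
  # the only aromatic is the planted binding tryptophan
  s <- flag_hars(annotated_seq("tA", "AAGSWNPAAA"))
  tm <- list(tA = template_record("tA", "SYN", s, 5L),
             tB = template_record("tB", "SYN",
                                  annotated_seq("tB", "MKVLIEDKLM")))
  tgt <- s
  alns <- align_all(tgt, tm)
  cands <- enumerate_candidates(select_candidates(alns, k = 2), tm)
  self <- cands[[which(vapply(cands, `[[`, "", "candidate_id") == "tA")]]
  expect_equal(mock_surface_scorer(tgt, self), -1.5)
})

test_that("the mock scorer matches its formula on an arbitrary candidate", {
  x <- make_ca(3, seed = 33)
  cands <- enumerate_candidates(x$ca, x$templates)
  cand <- cands[[length(cands)]]  # a double
  manual <- mean(vapply(seq_along(cand$alignments), function(i) {
    a <- cand$alignments[[i]]
    hars <- which(x$target$har_flags)
    hit <- sum(a$t_idx %in% hars & a$p_idx %in%
                 cand$templates[[i]]$known_binding_positions &
                 a$t_idx > 0 & a$p_idx > 0)
    1 - 2 * a$ident / a$n_columns -
      0.5 * (if (length(hars)) hit / length(hars) else 0)
  }, 0))
  expect_equal(mock_surface_scorer(x$target, cand), manual)
})

test_that("ranking is deterministic and equals a brute-force argmin", {
  x <- make_ca(5, seed = 44)
  cands <- enumerate_candidates(x$ca, x$templates)
  r1 <- rank_candidates(x$target, cands)
  r2 <- rank_candidates(x$target, cands)
  expect_equal(vapply(r1, `[[`, "", "candidate_id"),
               vapply(r2, `[[`, "", "candidate_id"))
  z <- vapply(r1, `[[`, 0, "z_score")
  expect_true(all(diff(z) >= 0))
  best <- select_best(r1)
  expect_equal(best$z_score,
               min(vapply(cands, function(c)
                 mock_surface_scorer(x$target, c), 0)))
})

test_that("a failing scorer skips the candidate without killing the run", {
  x <- make_ca(3, seed = 55)
  cands <- enumerate_candidates(x$ca, x$templates)
  poison <- cands[[1]]$candidate_id
  scorer <- function(target, cand) {
    if (cand$candidate_id == poison) stop("engine crashed")
    mock_surface_scorer(target, cand)
  }
  expect_warning(r <- rank_candidates(x$target, cands, scorer), "skipped")
  expect_false(poison %in% vapply(r, `[[`, "", "candidate_id"))
  expect_length(r, length(cands) - 1L)
})

test_that("select_best breaks z ties in favor of fewer templates", {
  x <- make_ca(3, seed = 66)
  cands <- enumerate_candidates(x$ca, x$templates)
  flat <- rank_candidates(x$target, cands, scorer = function(t, c) 0)
  best <- select_best(flat)
  expect_equal(best$origin, "single")
  expect_error(select_best(list()), "no scored")
})

test_that("injected z-score tables override the scorer", {
  x <- make_ca(3, seed = 77)
  cands <- enumerate_candidates(x$ca, x$templates)
  ztab <- data.frame(candidate_id = cands[[2]]$candidate_id,
                     z_score = -99)
  r <- rank_candidates(x$target, cands, z_table = ztab)
  expect_equal(r[[1]]$candidate_id, cands[[2]]$candidate_id)
  expect_equal(r[[1]]$z_score, -99)
})

test_that("a target identical to a template selects that template", {
  tm <- generate_template_set(6, length = 60, seed = 88)
  tgt <- tm[[3]]$seq
  alns <- align_all(tgt, tm)
  ca <- select_candidates(alns, k = 3)
  best <- select_best(rank_candidates(tgt, enumerate_candidates(ca, tm)))
  expect_true(tm[[3]]$template_id %in% best$template_ids)
})

test_that("candidate tables carry origin, z and rank", {
  x <- make_ca(3, seed = 99)
  r <- rank_candidates(x$target, enumerate_candidates(x$ca, x$templates))
  df <- candidate_table(r)
  expect_equal(df$rank, seq_len(nrow(df)))
  expect_true(all(df$origin %in% c("single", "double")))
})
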