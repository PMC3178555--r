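test_that("template generation is byte-identical per seed", {
  a <- generate_template_set(3, seed = 17)
  b <- generate_template_set(3, seed = 17)
  expect_identical(a, b)
  c <- generate_template_set(3, seed = 18)
  expect_false(identical(a, c))
})

test_that("every planted motif center is a called HAR", {
  tm <- generate_template_set(8, length = 90, n_binding = 2, seed = 101)
  for (t in tm) {
    centers <- attr(t$seq, "planted_centers")
    expect_equal(centers, t$known_binding_positions)
    calls <- identify_hars(t$seq)
    expect_true(all(centers %in% calls$position[calls$is_har]))
    expect_true(all(vapply(centers, function(p)
      har_score(t$seq, p), 0L) >= 97))
  }
})

test_that("motif packing limits are enforced", {
  expect_error(generate_template_set(1, length = 20, n_binding = 5),
               "pack")
  tm <- generate_template_set(2, length = 30, n_binding = 0, seed = 1)
  expect_equal(tm[[1]]$known_binding_positions, integer(0))
})

test_that("mutation is a seeded no-op at zero rates", {
  tm <- generate_template_set(1, seed = 7)
  s <- tm[[1]]$seq
  m0 <- mutate_sequence(s, sub_rate = 0, indel_rate = 0, seed = 5)
  expect_equal(m0$residues, s$residues)
  m1 <- mutate_sequence(s, sub_rate = 0.4, indel_rate = 0.05, seed = 5)
  m2 <- mutate_sequence(s, sub_rate = 0.4, indel_rate = 0.05, seed = 5)
  expect_identical(m1, m2)
})

test_that("preserved motif windows survive heavy mutation", {
  tm <- generate_template_set(4, length = 80, seed = 13)
  for (t in tm) {
    mut <- mutate_sequence(t$seq, sub_rate = 0.8, indel_rate = 0.05,
                           seed = 23, preserve_motifs = TRUE)
    old_ctr <- attr(t$seq, "planted_centers")
    new_ctr <- attr(mut, "planted_centers")
    expect_length(new_ctr, length(old_ctr))
    oldc <- seq_chars(t$seq); newc <- seq_chars(mut)
    for (i in seq_along(old_ctr))
      expect_equal(newc[(new_ctr[i] - 2):(new_ctr[i] + 2)],
                   oldc[(old_ctr[i] - 2):(old_ctr[i] + 2)])
  }
})

test_that("mean identity to the source decreases with the divergence level", {
  tm <- generate_template_set(1, length = 100, seed = 37)
  src <- tm[[1]]$seq
  mean_ident <- vapply(c(0, 0.2, 0.4, 0.6), function(rate) {
    pid <- vapply(1:20, function(i) {
      mut <- mutate_sequence(src, sub_rate = rate, indel_rate = 0,
                             seed = 1000 + i)
      a <- align_pair(mut, src)
      100 * a$ident / a$n_columns
    }, 0)
    mean(pid)
  }, 0)
  expect_true(all(diff(mean_ident) < 0))
  expect_equal(mean_ident[1], 100)
})

test_that("benchmarks cover every target in the truth table", {
  bench <- generate_benchmark(n_templates = 5, n_targets_per_template = 2,
                              seed = 41)
  expect_length(bench$targets, 10L)
  expect_setequal(bench$truth$target_id, names(bench$targets))
  expect_true(all(bench$truth$template_id %in% names(bench$templates)))
  # determinism of the full benchmark
  expect_identical(bench, generate_benchmark(n_templates = 5,
                                             n_targets_per_template = 2,
                                             seed = 41))
})

test_that("a zero-divergence benchmark aligns back at full identity", {
  bench <- generate_benchmark(n_templates = 2, n_targets_per_template = 1,
                              divergence = 0, indel_rate = 0,
                              track_flip_rate = 0, seed = 53)
  for (i in seq_len(nrow(bench$truth))) {
    tgt <- bench$targets[[bench$truth$target_id[i]]]
    src <- bench$templates[[bench$truth$template_id[i]]]
    a <- align_pair(tgt, src)
    expect_equal(100 * a$ident / a$n_columns, 100)
  }
})

test_that("benchmarks round-trip to disk as standard files", {
  bench <- generate_benchmark(n_templates = 2, n_targets_per_template = 1,
                              seed = 59)
  dir <- withr::local_tempdir()
  write_benchmark(bench, dir)
  targets <- read_fasta(file.path(dir, "targets.fasta"))
  expect_setequal(names(targets), names(bench$targets))
  tracks <- read_secstruct_track(
    file.path(dir, "tracks", paste0(names(targets)[1], ".track")),
    targets[[1]])
  expect_equal(tracks$states, bench$targets[[names(targets)[1]]]$states)
  templates <- read_template_table(file.path(dir, "templates.csv"))
  expect_setequal(names(templates), names(bench$templates))
})
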