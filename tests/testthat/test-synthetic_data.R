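test_that("generation is deterministic given the seed", {
  p <- sim_params(n_transcripts = 40, depth = 2000, seed = 11,
                  organs = "leaves", replicates = 1)
  r1 <- generate_reference(p)
  r2 <- generate_reference(p)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$truth, r2$truth)
  l1 <- simulate_libraries(r1, p, assays = "m6A")
  l2 <- simulate_libraries(r2, p, assays = "m6A")
  expect_identical(as.data.frame(l1[[1]]$fragments),
                   as.data.frame(l2[[1]]$fragments))
})

test_that("every planted site carries its RRACH 5-mer on the sense strand", {
  ref <- generate_reference(sim_params(n_transcripts = 120, seed = 12))
  seqs <- transcript_sequences(ref$genome, ref$models)
  s <- ref$truth$sites
  fivemers <- unname(substr(as.character(seqs[s$transcript_id]),
                            s$pos - 1, s$pos + 3))
  expect_identical(fivemers, s$motif)
  expect_true(all(grepl("^[AG][AG]AC[ACT]$", fivemers)))
})

test_that("pure stop-codon placement puts all sites in the stop/3'UTR window", {
  ref <- sim_stop()$ref
  s <- ref$truth$sites
  tx <- ref$models$tx
  m <- match(s$transcript_id, tx$transcript_id)
  mrna <- tx$biotype[m] == "mRNA"
  expect_gte(sum(mrna), 100)
  expect_true(all(s$pos[mrna] >= tx$stop_pos[m][mrna] - 100))
})

test_that("capture model honors the site-coverage rule", {
  # no sites and background off -> zero m6A fragments anywhere
  p0 <- sim_params(n_transcripts = 30, depth = 500, seed = 13,
                   organs = "leaves", replicates = 1,
                   frac_methylated = 0.5, p_specific = 1, p_nonspecific = 0,
                   te_fraction = 0)
  ref <- generate_reference(p0)
  libs <- simulate_libraries(ref, p0, assays = "m6A")
  pr <- project_fragments(libs[[1]]$fragments, ref$models)
  sites <- split(ref$truth$sites$pos, ref$truth$sites$transcript_id)
  covers <- vapply(seq_len(nrow(pr)), function(i) {
    sp <- sites[[pr$transcript_id[i]]]
    !is.null(sp) && any(sp >= pr$start[i] & sp < pr$end[i])
  }, logical(1))
  expect_true(all(covers))   # p_nonspecific = 0: every fragment covers a site

  # transcripts without sites collect no fragments when background is off
  unmeth <- ref$truth$transcripts$transcript_id[!ref$truth$transcripts$methylated]
  expect_false(any(pr$transcript_id %in% unmeth))
})

test_that("background fraction of the captured library stays near the <1% design", {
  rec <- sim_recovery()
  pr <- project_fragments(rec$libs$leaves_rep1_m6A$fragments, rec$ref$models)
  sites <- split(rec$ref$truth$sites$pos, rec$ref$truth$sites$transcript_id)
  covers <- vapply(seq_len(nrow(pr)), function(i) {
    sp <- sites[[pr$transcript_id[i]]]
    !is.null(sp) && any(sp >= pr$start[i] & sp < pr$end[i])
  }, logical(1))
  expect_lt(mean(!covers), 0.02)
})

test_that("mRNA-seq counts track expression weights", {
  rec <- sim_recovery()
  pr <- project_fragments(rec$libs$leaves_rep1_mRNA$fragments, rec$ref$models)
  ids <- rec$ref$models$tx$transcript_id
  cnt <- as.integer(table(factor(pr$transcript_id, levels = ids)))
  rho <- stats::cor(cnt, rec$ref$truth$transcripts$expr_weight,
                    method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("m6A coverage concentrates around planted sites", {
  rec <- sim_recovery()
  ref <- rec$ref
  pr <- project_fragments(rec$libs$leaves_rep1_m6A$fragments, ref$models)
  s <- ref$truth$sites
  near <- far <- nearlen <- farlen <- 0
  for (id in unique(s$transcript_id)[1:80]) {
    L <- ref$models$tx$tx_len[ref$models$tx$transcript_id == id]
    v <- integer(L)
    pp <- pr[pr$transcript_id == id, ]
    for (i in seq_len(nrow(pp)))
      v[(pp$start[i] + 1):pp$end[i]] <- v[(pp$start[i] + 1):pp$end[i]] + 1L
    idx <- unique(unlist(lapply(s$pos[s$transcript_id == id], function(x)
      max(1, x - 74):min(L, x + 76))))
    near <- near + sum(v[idx]); nearlen <- nearlen + length(idx)
    far <- far + sum(v[-idx]); farlen <- farlen + (L - length(idx))
  }
  expect_gte((near / nearlen) / (far / farlen), 5)
})

test_that("TE transcripts are sampled only within their sub-intervals", {
  p <- sim_params(n_transcripts = 60, depth = 2e4, seed = 14,
                  organs = "leaves", replicates = 1, te_fraction = 0.2)
  ref <- generate_reference(p)
  libs <- simulate_libraries(ref, p, assays = "mRNA")
  pr <- project_fragments(libs[[1]]$fragments, ref$models)
  tw <- ref$truth$te_windows
  for (id in unique(tw$transcript_id)) {
    pp <- pr[pr$transcript_id == id, ]
    if (!nrow(pp)) next
    w <- tw[tw$transcript_id == id, ]
    inside <- vapply(seq_len(nrow(pp)), function(i)
      any(pp$start[i] >= w$start & pp$end[i] <= w$end), logical(1))
    expect_true(all(inside))
  }
})

test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(p_nonspecific = 0.95), "p_nonspecific")
  p <- sim_params(n_transcripts = 10, seed = 15, organs = "leaves",
                  replicates = 1)
  ref <- generate_reference(p)
  expect_error(simulate_libraries(ref, p, depth = 0), "zero-depth")
})
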