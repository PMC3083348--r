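test_that("candidate sites enumerate every Ser/Thr in ascending order", {
  expect_equal(
    extract_candidate_sites(protein("p", "MASTG"))$position,
    c(3L, 4L)
  )
  expect_equal(nrow(extract_candidate_sites(protein("p", "MAAAG"))), 0L)

  set.seed(3)
  placed <- sort(sample(60, 7))
  ch <- sample(setdiff(og_alphabet()[1:20], c("S", "T")), 60, replace = TRUE)
  ch[placed] <- sample(c("S", "T"), 7, replace = TRUE)
  sites <- extract_candidate_sites(protein("p", paste(ch, collapse = "")))
  expect_equal(sites$position, placed)
  expect_equal(sites$residue, ch[placed])
  expect_true(all(sites$label == "unlabeled"))
})

test_that("windows are centred on the site and padded past the terminals", {
  cfg5 <- window_config(5)
  w <- extract_window(protein("p", "STAAAAAAAA"), 1, cfg5)
  expect_equal(w, c(rep(og_eos(), 5), "S", "T", "A", "A", "A", "A"))

  # site exactly n+1 from both ends of a length 2n+1 sequence: no padding
  seqs <- paste0("AAAAA", "S", "GGGGG")
  w2 <- extract_window(protein("p", seqs), 6, cfg5)
  expect_equal(w2, strsplit(seqs, "")[[1]])

  expect_equal(
    extract_window(protein("p", "MASTG"), 4, window_config(2)),
    c("A", "S", "T", "G", og_eos())
  )
  expect_error(
    extract_window(protein("p", "MASTG"), 2, cfg5),
    class = "og_contract_error"
  )
})

test_that("one-hot blocks follow the declared alphabet order", {
  cfg <- window_config(1)
  v <- sparse_encode(c("A", "S", og_eos()), cfg)
  expect_equal(v[1:21], c(1L, rep(0L, 20)))             # Ala: 1 then twenty 0s
  expect_equal(v[43:63], c(rep(0L, 20), 1L))            # end-of-sequence: last slot
  expect_equal(which(v[22:42] == 1L), match("S", og_alphabet()))
  expect_error(sparse_encode(c("A", "S", "?"), cfg), class = "og_encoding_error")
  expect_error(sparse_encode(c("A", "S"), cfg), class = "og_contract_error")
  # permissive X becomes an all-zero block, length unchanged
  vx <- sparse_encode(c("X", "S", "A"), cfg)
  expect_equal(length(vx), 63L)
  expect_equal(sum(vx[1:21]), 0L)
})

test_that("encoding invariants hold on fuzzed windows and decoding inverts encoding", {
  set.seed(42)
  cfg <- window_config(5)
  for (i in 1:25) {
    w <- sample(og_alphabet(), 11, replace = TRUE)
    v <- sparse_encode(w, cfg)
    expect_length(v, 231L)
    expect_equal(sum(v), 11L)
    blocks <- matrix(v, nrow = 21)
    expect_true(all(colSums(blocks) == 1L))
    expect_equal(decode_window(v, cfg), w)
  }
  for (n in c(1, 3, 12)) {
    cfg_n <- window_config(n)
    w <- sample(og_alphabet(), 2 * n + 1, replace = TRUE)
    expect_length(sparse_encode(w, cfg_n), 21 * (2 * n + 1))
    expect_equal(sum(sparse_encode(w, cfg_n)), 2 * n + 1)
  }
})

test_that("window extraction mirrors under sequence reversal", {
  set.seed(7)
  for (i in 1:10) {
    len <- sample(8:40, 1)
    ch <- sample(og_alphabet()[1:20], len, replace = TRUE)
    pos <- sample(len, 1)
    ch[pos] <- "S"
    fwd <- protein("f", paste(ch, collapse = ""))
    rev <- protein("r", paste(base::rev(ch), collapse = ""))
    cfg <- window_config(4)
    w1 <- extract_window(fwd, pos, cfg)
    w2 <- extract_window(rev, len - pos + 1, cfg)
    expect_equal(w2, base::rev(w1))
  }
})

test_that("window half-width is validated", {
  expect_error(window_config(0), class = "og_config_error")
  expect_error(window_config(26), class = "og_config_error")
  expect_silent(window_config(25))
})

test_that("dataset assembly labels annotated sites positive and the rest negative", {
  p <- protein("p1", "MASTGSATAA")      # S/T at 3, 4, 6, 8
  ann <- annotation("p1", 3, "S")
  d <- assemble_dataset(p, ann, window_config(2))
  expect_equal(nrow(d), 4L)
  expect_equal(sum(d$label == "positive"), 1L)
  expect_equal(sum(d$label == "negative"), 3L)
  expect_equal(d$position[d$label == "positive"], 3L)

  d0 <- assemble_dataset(p, NULL, window_config(2))
  expect_true(all(d0$label == "negative"))

  x <- og_features(d)
  expect_equal(dim(x), c(4L, 105L))
  expect_true(all(rowSums(x) == 5L))
  # feature rows agree with encoding each window directly
  for (i in seq_len(nrow(d))) {
    w <- extract_window(p, d$position[[i]], window_config(2))
    expect_equal(unname(x[i, ]), sparse_encode(w, window_config(2)))
  }
})

test_that("instance export writes the dense text matrix format", {
  p <- protein("p1", "MASTG")
  d <- assemble_dataset(p, NULL, window_config(1))
  out <- withr::local_tempfile(fileext = ".csv")
  export_instances(d, out)
  lines <- readLines(out)
  expect_length(lines, 3L)
  first <- strsplit(lines[[2]], ",")[[1]]
  expect_equal(first[1:3], c("p1", "3", "negative"))
  expect_equal(as.integer(first[-(1:3)]), sparse_encode(c("A", "S", "T"), window_config(1)))
})
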