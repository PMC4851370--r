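test_that("revcomp complements, reverses and rejects bad symbols", {
  expect_equal(revcomp("TGACG"), "CGTCA")
  expect_equal(revcomp("AAGAAT"), "ATTCTT")
  expect_equal(revcomp("N"), "N")
  expect_error(revcomp("ACGU"), "position 4")
  set.seed(11)
  for (i in 1:20) {
    x <- random_dna(sample(1:60, 1))
    expect_equal(revcomp(revcomp(x)), x)
    expect_equal(revcomp(x), bs_revcomp(x))
  }
})

test_that("hexamer anchors honour the degenerate first position", {
  ref <- reference_motif()
  expect_equal(find_hexamer_sites("GGAAGAATGG", ref, both_strands = FALSE),
               data.frame(position = 0L + 2L, strand = "+"),
               ignore_attr = TRUE)
  expect_equal(find_hexamer_sites("GGCAGAATGG", ref, both_strands = FALSE)$position, 2L)
  expect_equal(nrow(find_hexamer_sites("GGGAGAATGG", ref, both_strands = FALSE)), 0L)
  # all four first letters, exhaustively
  hits <- vapply(c("A", "C", "G", "T"), function(b)
    nrow(find_hexamer_sites(paste0("GG", b, "AGAATGG"), ref,
                            both_strands = FALSE)), integer(1))
  expect_equal(unname(hits), c(1L, 1L, 0L, 1L))
  # reverse-strand hit reported in forward coordinates
  s <- paste0("GG", revcomp("AAGAAT"), "GG")
  h <- find_hexamer_sites(s, ref)
  expect_equal(h$position, 2L)
  expect_equal(h$strand, "-")
  # overlapping occurrences are all found
  h2 <- find_hexamer_sites("AAGAATAGAAT", ref, both_strands = FALSE)
  expect_true(all(c(0L, 5L) %in% h2$position))
})

test_that("window extraction aligns the hexamer with the reference frame", {
  ref <- reference_motif()
  w <- extract_window(ref$sequence, ref$hexamer_offset, "+", ref)
  expect_equal(w$window_seq, ref$sequence)
  expect_equal(w$window_start, 0L)
  # hexamer too close to the start for a non-zero offset
  ref5 <- reference_motif(paste0("GGGGG", substr(reference_motif()$sequence, 1, 28)),
                          hexamer_offset = 5L)
  expect_null(extract_window(paste0("GG", "AAGAAT", strrep("G", 40)), 2L, "+", ref5))
  # minus-strand window equals revcomp of the forward slice (oracle check)
  seq <- paste0(strrep("G", 10), revcomp(ref$sequence), strrep("G", 10))
  hit <- find_hexamer_sites(seq, ref)
  expect_equal(hit$strand, "-")
  w2 <- extract_window(seq, hit$position, "-", ref)
  expect_equal(w2$window_seq,
               bs_revcomp(substr(seq, w2$window_start + 1, w2$window_start + 33)))
  expect_equal(w2$window_seq, ref$sequence)
})

test_that("deviation counting is Hamming with the degeneracy carve-out", {
  ref <- reference_motif()
  expect_equal(count_deviations(ref$sequence, ref), 0L)
  # three substitutions at non-degenerate positions
  w <- strsplit(ref$sequence, "")[[1]]
  for (i in c(8, 22, 30)) w[i] <- setdiff(c("A", "C", "G", "T"), w[i])[1]
  expect_equal(count_deviations(paste(w, collapse = ""), ref), 3L)
  # first hexamer position A->C is not a deviation; A->G is
  wc <- ref$sequence; substr(wc, 1, 1) <- "C"
  expect_equal(count_deviations(wc, ref), 0L)
  wg <- ref$sequence; substr(wg, 1, 1) <- "G"
  expect_equal(count_deviations(wg, ref), 1L)
  # N always deviates
  wn <- ref$sequence; substr(wn, 10, 10) <- "N"
  expect_equal(count_deviations(wn, ref), 1L)
  expect_error(count_deviations("ACGT", ref), "length")
  # monotone under additional substitutions
  set.seed(3)
  w <- strsplit(ref$sequence, "")[[1]]
  prev <- 0L
  for (i in sample(7:33)) {
    w[i] <- sample(setdiff(c("A", "C", "G", "T"), w[i]), 1)
    d <- count_deviations(paste(w, collapse = ""), ref)
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("core detection works on both strands and dies by two-nt exchange", {
  ref <- reference_motif()
  win_plus <- paste0("TGACG", substr(ref$sequence, 6, 33))
  expect_equal(has_tga_core(win_plus, ref), list(core_present = TRUE, core_strand = "+"))
  expect_equal(has_tga_core(ref$sequence, ref),
               list(core_present = TRUE, core_strand = "-"))
  # two-nucleotide core exchange abolishes recognition
  broken <- sub("CGTCA", "CGGGA", ref$sequence, fixed = TRUE)
  expect_equal(has_tga_core(broken, ref),
               list(core_present = FALSE, core_strand = "none"))
  # leftmost occurrence wins when both strands match
  both <- paste0("TGACG", "AA", "CGTCA", strrep("T", 21))
  expect_equal(has_tga_core(both, ref)$core_strand, "+")
  # plus-strand-only policy ignores the reverse-orientation core
  p1 <- classifier_params(core_both_strands = FALSE)
  expect_false(has_tga_core(ref$sequence, ref, p1)$core_present)
})

test_that("classification boundary sits between 7 and 8 deviations", {
  ref <- reference_motif()
  params <- classifier_params()
  expect_equal(classify_window(ref$sequence, ref, params)$motif_class, "FULL")
  # boundary sweep with the core intact
  classes <- vapply(0:22, function(k) {
    g <- gen_intron(ref, length = 33L,
                    planted = data.frame(position = 0L, deviations = k,
                                         core_intact = TRUE),
                    seed = 100L + k)
    classify_window(g$sequence[[1]], ref, params)$motif_class
  }, character(1))
  expect_equal(max(which(classes == "FULL")) - 1L, 7L)
  expect_true(all(classes[9:23] == "PARTIAL"))
  # core absent is always PARTIAL, flagged canonical above 15 deviations
  g16 <- gen_intron(ref, length = 33L,
                    planted = data.frame(position = 0L, deviations = 16L,
                                         core_intact = FALSE), seed = 5L)
  call16 <- classify_window(g16$sequence[[1]], ref, params)
  expect_equal(call16$motif_class, "PARTIAL")
  expect_true(call16$canonical_partial)
  g5 <- gen_intron(ref, length = 33L,
                   planted = data.frame(position = 0L, deviations = 5L,
                                        core_intact = FALSE), seed = 6L)
  call5 <- classify_window(g5$sequence[[1]], ref, params)
  expect_equal(call5$motif_class, "PARTIAL")
  expect_false(call5$canonical_partial)
})

test_that("scan finds planted motifs, reports ABSENT, and breaks ties", {
  ref <- reference_motif()
  g <- gen_intron(ref, length = 500L,
                  planted = data.frame(position = 100L, deviations = 0L,
                                       core_intact = TRUE), seed = 21L)
  sc <- scan_sequence(g$sequence[[1]], ref, seq_id = "planted")
  expect_equal(sc$best$motif_class, "FULL")
  expect_equal(sc$best$window_start, 100L)
  expect_equal(sc$best$deviations, 0L)
  # no anchor at all
  expect_equal(scan_sequence(strrep("G", 50), ref)$best$motif_class, "ABSENT")
  expect_error(scan_sequence("", ref), "empty")
  # two core-intact candidates: fewer deviations wins
  g2 <- gen_intron(ref, length = 400L,
                   planted = data.frame(position = c(50L, 200L),
                                        deviations = c(5L, 2L),
                                        core_intact = c(TRUE, TRUE)),
                   seed = 8L)
  sc2 <- scan_sequence(g2$sequence[[1]], ref)
  expect_equal(sc2$best$window_start, 200L)
  expect_equal(sc2$best$deviations, 2L)
  expect_equal(nrow(sc2$calls) >= 2L, TRUE)
})

test_that("scanning the reverse complement mirrors the call set", {
  ref <- reference_motif()
  set.seed(17)
  for (i in 1:10) {
    g <- gen_intron(ref, length = 300L,
                    planted = data.frame(position = sample(0:260, 1),
                                         deviations = sample(0:5, 1),
                                         core_intact = TRUE), seed = 300L + i)
    seq <- g$sequence[[1]]
    a <- scan_sequence(seq, ref)$calls
    b <- scan_sequence(revcomp(seq), ref)$calls
    expect_equal(nrow(a), nrow(b))
    if (!nrow(a)) next
    bm <- b
    bm$window_start <- nchar(seq) - 33L - bm$window_start
    bm$strand <- ifelse(bm$strand == "+", "-", "+")
    key <- function(d) {
      d <- d[order(d$window_start, d$strand), ]
      paste(d$window_start, d$strand, d$deviations, d$motif_class)
    }
    expect_equal(key(a), key(bm))
  }
})

test_that("exhaustive all-window oracle agrees with the anchored scan", {
  ref <- reference_motif()
  set.seed(99)
  for (i in 1:25) {
    seq <- random_dna(sample(40:200, 1))
    if (i %% 3 == 0) {
      # ensure some sequences contain a real candidate (a broken core
      # implies at least the two exchanged core nucleotides deviate)
      pos <- sample(0:(nchar(seq) - 33), 1)
      core_ok <- sample(c(TRUE, FALSE), 1)
      g <- gen_intron(ref, length = nchar(seq),
                      planted = data.frame(position = pos,
                                           deviations = sample(if (core_ok) 0:10 else 2:10, 1),
                                           core_intact = core_ok),
                      seed = 900L + i)
      seq <- g$sequence[[1]]
    }
    got <- scan_sequence(seq, ref)$best
    want <- oracle_scan(seq, ref)
    expect_equal(got$motif_class, want$motif_class)
    if (want$motif_class != "ABSENT") {
      expect_equal(got$window_start, want$window_start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$deviations, want$deviations)
    }
  }
})

test_that("FASTA scanning and YAML config round the module out", {
  ref <- reference_motif()
  g1 <- gen_intron(ref, planted = data.frame(position = 200L, deviations = 3L,
                                             core_intact = TRUE), seed = 41L)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">intron_a", g1$sequence[[1]], ">empty_bg", strrep("G", 80)), fa)
  calls <- scan_fasta(fa, ref)
  expect_equal(calls$motif_class[calls$seq_id == "intron_a"], "FULL")
  expect_equal(calls$motif_class[calls$seq_id == "empty_bg"], "ABSENT")
  expect_true(all(calls$best_flag))
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("reference:",
               paste0("  sequence: ", ref$sequence),
               "  hexamer_offset: 0",
               "  degenerate_positions:",
               "    '0': ACT",
               "params:",
               "  max_dev_full: 5"), cfg)
  conf <- read_motif_config(cfg)
  expect_equal(conf$ref$sequence, ref$sequence)
  expect_equal(conf$params$max_dev_full, 5L)
})
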