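# Shared fixture builders (everything generated in code at test time).

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a repeat-free guide (plain random sequence wrapped as a guide object)
plain_guide <- function(n, seed = 1, id = "plain", class = "SHORT") {
  guide_haplotype(id, rand_dna(n, seed), class)
}

# simple uniform error-free read pairs straight off a sequence
simple_pairs <- function(seq, depth = 30, rl = 150, frag = 400, seed = 1) {
  tr <- list(id = "t", sequence = seq)
  simulate_reads(tr, read_sim_params(read_length = rl, depth_fold = depth,
                                     fragment_mean = frag, fragment_sd = 60,
                                     per_base_error = 0, seed = seed))$pairs
}

# read_pairs data frame from parallel vectors
pairs_df <- function(seq1, seq2, qual1 = NULL, qual2 = NULL,
                     ids = sprintf("p%03d", seq_along(seq1))) {
  q <- function(s, qq) if (is.null(qq))
    vapply(nchar(s), function(n) strrep("I", n), character(1)) else qq
  out <- data.frame(id = ids, seq1 = seq1, qual1 = q(seq1, qual1),
                    seq2 = seq2, qual2 = q(seq2, qual2),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

phred_string <- function(q) {
  intToUtf8(rep(q[1], q[2]) + 33L)
}

# independent brute-force trimmer used as the oracle
trim_oracle <- function(seq, qual, lead = 3, win = 4, meanq = 15) {
  q <- utf8ToInt(qual) - 33L
  b <- strsplit(seq, "")[[1]]
  keep <- rep(TRUE, length(q))
  i <- 1
  while (i <= length(q) && (q[i] < lead || b[i] == "N")) { keep[i] <- FALSE; i <- i + 1 }
  j <- length(q)
  while (j >= i && (q[j] < lead || b[j] == "N")) { keep[j] <- FALSE; j <- j - 1 }
  a <- i; e <- j
  if (e - a + 1 >= win) {
    for (w in a:(e - win + 1)) {
      if (mean(q[w:(w + win - 1)]) < meanq) { e <- w - 1; break }
    }
  }
  if (e < a) "" else substr(seq, a, e)
}

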