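# Independent brute-force oracles, kept deliberately naive and separate
# from the package's vectorized implementations.

ORACLE_BASES <- c("A", "C", "G", "T")

# Per-column counting + per-site summation, plain loops.
oracle_build_model <- function(sites, pseudocount = 0) {
  L <- nchar(sites[1])
  N <- length(sites)
  mat <- do.call(rbind, strsplit(sites, ""))
  f <- matrix(0, 4, L, dimnames = list(ORACLE_BASES, NULL))
  for (l in 1:L) for (b in ORACLE_BASES)
    f[b, l] <- (sum(mat[, l] == b) + pseudocount) / (N + 4 * pseudocount)
  w <- 2 + log2(f)
  score1 <- function(s) {
    ch <- strsplit(s, "")[[1]]
    tot <- 0
    for (l in 1:L) tot <- tot + w[ch[l], l]
    tot
  }
  sc <- vapply(sites, score1, 0, USE.NAMES = FALSE)
  mu <- mean(sc)
  list(f = f, w = w, scores = sc, mu = mu,
       sigma_pop = sqrt(mean((sc - mu)^2)), sigma_samp = sd(sc),
       score1 = score1,
       rseq = sum(ifelse(f > 0, f * w, 0)))
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Exhaustive both-strand window enumeration with the same reporting rules:
# strict > threshold, skip non-ACGT windows, same-window dedupe to the
# better strand (ties -> +).
oracle_scan <- function(w, seq, threshold) {
  L <- ncol(w)
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  rows <- list()
  if (n >= L) for (i in 1:(n - L + 1)) {
    win <- chars[i:(i + L - 1)]
    if (any(!win %in% ORACLE_BASES)) next
    sf <- 0
    for (l in 1:L) sf <- sf + w[win[l], l]
    rcwin <- strsplit(chartr("ACGT", "TGCA", paste(rev(win), collapse = "")), "")[[1]]
    sr <- 0
    for (l in 1:L) sr <- sr + w[rcwin[l], l]
    pf <- sf > threshold; pr <- sr > threshold
    if (pf && pr) { if (sf >= sr - 1e-9) pr <- FALSE else pf <- FALSE }
    if (pf) rows[[length(rows) + 1]] <-
      data.frame(start = i - 1, strand = "+", score = sf,
                 site_seq = paste(win, collapse = ""), stringsAsFactors = FALSE)
    if (pr) rows[[length(rows) + 1]] <-
      data.frame(start = i - 1, strand = "-", score = sr,
                 site_seq = paste(rcwin, collapse = ""), stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(start = integer(), strand = character(), score = numeric(),
                  site_seq = character(), stringsAsFactors = FALSE)
}

# Closed-form simple-regression normal equations.
oracle_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  pred <- intercept + slope * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - yb)^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Chain-scan operon oracle written as an explicit loop.
oracle_operons <- function(genes, gap_max = 100) {
  g <- genes[order(genes$contig_id, genes$start), ]
  ids <- integer(nrow(g))
  cur <- 0L
  for (i in seq_len(nrow(g))) {
    if (i == 1L ||
        g$contig_id[i] != g$contig_id[i - 1] ||
        g$strand[i] != g$strand[i - 1] ||
        g$start[i] - g$end[i - 1] >= gap_max) cur <- cur + 1L
    ids[i] <- cur
  }
  split(g$gene_id, ids)
}

# All-pairs nearest-start association with the documented tie rule.
oracle_link <- function(hits, genes, upstream = 300, downstream = 50,
                        contig_len = Inf) {
  out <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    g <- genes[genes$contig_id == h$contig_id, ]
    if (nrow(g) == 0) next
    mid <- (h$start + h$end) / 2
    tss <- ifelse(g$strand == "+", g$start, g$end - 1)
    ws <- pmax(ifelse(g$strand == "+", g$start - upstream, g$end - downstream), 0)
    we <- pmin(ifelse(g$strand == "+", g$start + downstream, g$end + upstream),
               contig_len)
    d <- abs(mid - tss)
    cand <- which(d == min(d))
    if (length(cand) > 1) {
      inw <- h$start >= ws[cand] & h$end <= we[cand]
      if (sum(inw) == 1) cand <- cand[inw]
      else cand <- cand[order(g$start[cand], g$gene_id[cand])][1]
    }
    k <- cand[1]
    out[[length(out) + 1]] <- data.frame(
      row = i, gene_id = g$gene_id[k],
      distance = ifelse(g$strand[k] == "+", mid - tss[k], tss[k] - mid),
      in_promoter = h$start >= ws[k] & h$end <= we[k],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
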