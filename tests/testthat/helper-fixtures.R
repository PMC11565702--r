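# Shared fixture builders: every fixture is generated in code.

# minimal valid per-variant record table
makeRecords <- function(ids, beta, se, pval = NULL, ea = "A", oa = "G",
                        eaf = 0.3, chrom = "1", pos = NULL, n = 10000) {
  k <- length(ids)
  if (is.null(pos)) pos <- seq_len(k) * 1e6
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)),
                                  .Machine$double.xmin)
  data.frame(variant_id = ids, chromosome = rep_len(chrom, k),
             position = pos, effect_allele = rep_len(ea, k),
             other_allele = rep_len(oa, k), eaf = rep_len(eaf, k),
             beta = beta, se = rep_len(se, k), pval = pval,
             n = rep_len(n, k), stringsAsFactors = FALSE)
}

makeStats <- function(ids, beta, se, ..., traitId = "trait") {
  SummaryStats(makeRecords(ids, beta, se, ...), traitId = traitId)
}

# harmonized set straight from effect vectors
makeH <- function(bx, by, sx = 0.01, sy = 0.01,
                  ids = sprintf("rs%03d", seq_along(bx))) {
  HarmonizedSet(ids, bx, rep_len(sx, length(bx)), by,
                rep_len(sy, length(bx)))
}

# independently coded fixed-effects IVW as weighted mean of Wald ratios
oracleIvwFe <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  sum(w * (by / bx)) / sum(w)
}

# brute-force Cochran Q over ratios
oracleQ <- function(bx, by, sy) {
  ratio <- by / bx
  w <- bx^2 / sy^2
  theta <- sum(w * ratio) / sum(w)
  sum(w * (ratio - theta)^2)
}

# brute-force BH step-up: q_(i) = min over j >= i of p_(j) * m / j
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- (m / seq_len(m)) * p[o]
  for (i in seq_len(m - 1)) {
    i <- m - i
    q[i] <- min(q[i], q[i + 1])
  }
  pmin(q, 1)[order(o)]
}

# brute-force greedy clumping over an explicit r2 matrix
oracleClump <- function(df, r2mat, kb, r2max) {
  ord <- order(df$pval, df$variant_id)
  df <- df[ord, ]
  alive <- rep(TRUE, nrow(df))
  kept <- character()
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    kept <- c(kept, df$variant_id[i])
    for (j in seq_len(nrow(df))) {
      if (j <= i || !alive[j]) next
      if (df$chromosome[j] != df$chromosome[i]) next
      if (abs(df$position[j] - df$position[i]) > kb * 1000) next
      if (r2mat[df$variant_id[i], df$variant_id[j]] > r2max) alive[j] <- FALSE
    }
  }
  kept
}
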