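# Internal numerical and infrastructure helpers shared across modules.

# p-values must stay in (0, 1]; extreme z-scores would otherwise underflow to 0
.pclamp <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)

# two-sided normal-theory p from an estimate and its SE
.zp <- function(beta, se) .pclamp(2 * stats::pnorm(-abs(beta / se)))

.zcrit <- function(level = 0.95) stats::qnorm(1 - (1 - level) / 2)

# Run expr under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so seeded operations never perturb each other.
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Classed conditions so callers can branch on failure modes
# (e.g. mrchain_insufficient_instruments) rather than matching messages.
.mrStop <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(paste0("mrchain_", code), "mrchain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.mrWarn <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  warning(structure(
    class = c(paste0("mrchain_", code), "mrchain_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# 32-bit FNV-1a over a string, kept exact with 16-bit split multiplication
# (doubles only hold 53 bits); used for config provenance fingerprints.
.fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(paste(x, collapse = "\n"))))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    hLo <- h %% 65536
    hHi <- (h - hLo) / 65536
    h <- (hLo * p + ((hHi * p) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# full-precision decimal serialization: %.17g round-trips IEEE doubles exactly
.fmtNum <- function(x) {
  out <- ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out
}

.fmtInt <- function(x) {
  ifelse(is.na(x), "NA", format(x, scientific = FALSE, trim = TRUE))
}

.isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
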