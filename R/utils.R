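#' @keywords internal
"_PACKAGE"

# Canonical item ordering: PHQ-9 items then GAD-7 items, all scored 0-3.
default_item_names <- function(m = 16L) {
  if (m == 16L) {
    c(paste0("phq", 1:9), paste0("gad", 1:7))
  } else {
    paste0("item", seq_len(m))
  }
}

panel_item_cols <- function(panel) {
  setdiff(names(panel), c("subject_id", "wave"))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. With seed = NULL the global stream is
# used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character scalar; used to stamp report bundles
# with a config fingerprint without a digest dependency.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h as a double
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit multiply by the FNV prime, split so doubles stay exact
    h_lo <- h %% 65536
    h_hi <- (h - h_lo) / 65536
    h <- (((h_hi * 16777619) %% 65536) * 65536 + h_lo * 16777619) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_panelnet <- function(...) stop(..., call. = FALSE)

is_square <- function(x) is.matrix(x) && nrow(x) == ncol(x)

spectral_radius <- function(beta) max(Mod(eigen(beta, only.values = TRUE)$values))
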