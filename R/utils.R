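## Internal utilities: stage logging, reproducible seed streams, config hash.

aw_log_env <- new.env(parent = emptyenv())
aw_log_env$file <- NULL

#' Direct stage logging to an optional file
#'
#' Messages always go to stderr; when a file is set they are appended there
#' too. Call with `NULL` to stop file logging.
#'
#' @param path file path or `NULL`.
#' @return previous log file path, invisibly.
#' @export
aw_log_file <- function(path = NULL) {
  old <- aw_log_env$file
  aw_log_env$file <- path
  invisible(old)
}

## Stage-boundary logging: consort-style record counts in/out.
aw_log <- function(fmt, ...) {
  msg <- sprintf("[aromawise] %s", sprintf(fmt, ...))
  message(msg)
  if (!is.null(aw_log_env$file)) {
    cat(msg, "\n", file = aw_log_env$file, append = TRUE, sep = "")
  }
  invisible(msg)
}

## 32-bit FNV-1a over a character vector; returns 8-hex-digit string.
## Used for config fingerprints embedded in result files.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    ## xor affects only the low byte; h stays a double-held 32-bit value
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    ## h * 16777619 mod 2^32, split to stay within double precision
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

## Serialize an R object to a canonical character form for hashing.
canonical_chr <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm)) {
      ord <- order(nm)
      x <- x[ord]
      nm <- nm[ord]
    }
    paste0("{", paste(vapply(seq_along(x), function(i) {
      paste0(if (!is.null(nm)) nm[i] else "", ":", canonical_chr(x[[i]]))
    }, character(1)), collapse = ","), "}")
  } else {
    paste(format(x, digits = 15), collapse = ",")
  }
}

config_hash <- function(config) fnv1a32(canonical_chr(config))

#' Derive a reproducible per-stage seed from a root seed
#'
#' Each pipeline stage (and each matching round) draws from its own RNG
#' stream keyed by name, so adding a stage never perturbs the randomness of
#' earlier stages. The derived seed is a deterministic 31-bit integer.
#'
#' @param seed root integer seed.
#' @param stage character stage name.
#' @return integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  bytes <- as.integer(charToRaw(stage))
  h <- (abs(seed) %% 2147483647)
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

## Evaluate expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
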