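# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

cg_stop <- function(..., class = "citygreen_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

cg_warn <- function(..., class = "citygreen_warning") {
  warning(structure(class = c(class, "warning", "condition"),
                    list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    cg_stop(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    cg_stop(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    cg_stop(name, " must be >= ", lower)
  if (x > upper)
    cg_stop(name, " must be <= ", upper)
  invisible(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state was in place before, so seeded internals never
#' perturb the caller's random stream. A `NULL` seed evaluates the code
#' against the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# FNV-1a hash of a character scalar, returned as 8 hex digits. Used to stamp
# outputs with a configuration fingerprint without a hashing dependency.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte since b < 256; keep h a double mod 2^32
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
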