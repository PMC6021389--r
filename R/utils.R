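#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-seed from a master seed and a stage name
#'
#' All randomised operations in the package draw their seed from one master
#' seed plus the name of the operation, so adding a stage to a workflow never
#' shifts the random draws of another stage.
#'
#' @param seed master integer seed.
#' @param name character tag of the consuming operation.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  # djb2-style rolling hash kept below 2^31 so the result is a valid seed
  h <- 5381
  for (b in utf8ToInt(name)) h <- (h * 33 + b) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

# FNV-1a hash of a character scalar, returned as hex; used for config hashes
fnv1a_hex <- function(x) {
  stopifnot(is.character(x))
  h <- 5381
  for (b in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- (h * 33 + b) %% 2147483647
  }
  format(as.hexmode(h), width = 8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_adbn <- function(class, msg, ...) {
  stop(structure(class = c(class, "adbn_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# deterministic shuffle helper used by CV / splitting code
shuffled_indices <- function(n, seed) {
  set.seed(seed)
  sample.int(n)
}
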