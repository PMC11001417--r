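#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select bind_rows arrange group_by summarise ungroup left_join row_number
#' @importFrom purrr map map_dbl map_int map_lgl map2 pmap imap keep
#' @importFrom stats rnorm runif plogis qlogis median quantile
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed, fully specified RNG state, restoring the
# caller's state afterwards. All stochastic operations in the package go
# through this so that (config, seed) pairs are reproducible across platforms.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Hierarchical substream seed: mixes a root seed with a stream index so that
# item i's randomness does not depend on how many items are generated.
# Plain integer hash; stays strictly below 2^31.
child_seed <- function(root, i) {
  root <- abs(as.numeric(root)) %% 2147483647
  i <- abs(as.numeric(i)) %% 2147483647
  lo <- root %% 65536
  hi <- root %/% 65536
  as.integer((lo * 40503 + hi * 104729 + i * 2654435 + 97) %% 2147483629 + 1)
}

# Polynomial rolling hash of a character vector, hex string.
# Used for dataset fingerprints (identity, not cryptography).
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "|"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}


stop_field <- function(field, msg) {
  abort(sprintf("invalid configuration: field `%s` %s", field, msg),
        class = "cellcryst_config_error")
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# grayscale conversion: mean over channels of an RGB array
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) return(rowMeans(img, dims = 2L))
  abort("expected a matrix or an H x W x C array")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)  # x first: pmax/pmin copy attributes from arg 1
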