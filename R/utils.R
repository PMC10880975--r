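#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_invalid <- function(...) {
  stop(structure(class = c("dpc_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_divergence <- function(...) {
  stop(structure(class = c("dpc_divergence", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_positive_int <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    stop_invalid(name, " must be a strictly positive integer (got ",
                 deparse(substitute(x)), " = ", format(x), ")")
  as.integer(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

## soft-threshold operator for the L1 proximal step; subgradient at 0 is 0
soft_threshold <- function(x, t) {
  sign(x) * pmax(abs(x) - t, 0)
}

## row-major vectorization, origin top-left (matches the frame contract)
frame_to_vec <- function(frame) as.vector(t(frame))

vec_to_frame <- function(v, frame_shape) {
  matrix(v, nrow = frame_shape[1], ncol = frame_shape[2], byrow = TRUE)
}

## Ensure x is a column-matrix view (N x B); remembers if input was a vector
as_col <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1)
}

l2sq <- function(x) sum(x * x)

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

## Deterministic child seed derived from a parent seed and a label,
## kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.double(seed) * 7919 + h) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
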