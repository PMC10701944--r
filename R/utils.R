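#' @importFrom stats plogis qlogis rnorm runif rbinom rpois quantile sd
#'   binomial coef glm predict qnorm density pnorm var median setNames
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

sigmoid <- function(x) plogis(x)

logit <- function(p) qlogis(p)

## clamp probabilities away from 0/1 before taking logs/logits
clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

## row-wise softmax with an optional logical mask (FALSE -> weight 0)
softmax_rows <- function(x, mask = NULL) {
  if (!is.null(mask)) x[!mask] <- -Inf
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e[is.na(e)] <- 0
  s <- rowSums(e)
  s[s == 0] <- 1
  e / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop_arg(msg)

## deterministic child seeds: derive k integer seeds < 2^31 from one seed
derive_seeds <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) + 104729L * seq_len(k)) %% 2147483587L
}

is_binary01 <- function(x) all(x %in% c(0, 1))
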