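#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats pt p.adjust wilcox.test fisher.test rnbinom rlnorm
#'   runif model.matrix lm.fit setNames phyper dhyper
#' @importFrom utils read.delim write.table packageVersion
NULL

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' Each generator consumes its own stream so that adding or reordering
#' generators never perturbs the output of the others.
#'
#' @param seed master integer seed.
#' @param label fixed character label naming the stream.
#' @return An integer seed below 2^31.
#' @keywords internal
streamSeed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 65521
  as.integer((abs(as.numeric(seed)) %% 1000003) * 2011 + h * 131 + 17) %% 2147483629L
}

# Evaluate expr under a given seed without clobbering the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# TRUE when x is a whole-number scalar (integerish)
isCount <- function(x, positive = TRUE) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) &&
    (!positive || x > 0)
}
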