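#' @importFrom rlang .data abort warn .env
#' @importFrom stats setNames rexp rbinom rmultinom runif aov lm coef cor.test
#'   TukeyHSD pnorm p.adjust var sd rgamma
#' @importFrom utils head
NULL

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed (keeps all seeds < 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(vector("list", n))
  }
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

#' Region labels used throughout the package
#'
#' The five broad sampling regions: Siberia (SIB), North America (NAM),
#' Mesoamerica (MEA), South America Andes (SAA) and South America Lowlands
#' (SAL).
#' @export
region_labels <- function() c("SIB", "NAM", "MEA", "SAA", "SAL")

#' Native American region labels (all regions except Siberia)
#' @rdname region_labels
#' @export
native_regions <- function() c("NAM", "MEA", "SAA", "SAL")

hla_loci <- function() c("A", "B", "C", "DRB1")
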