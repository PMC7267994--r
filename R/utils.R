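#' @keywords internal
"_PACKAGE"

## Relation-class constants used across the package.
CPR_GROUPS <- paste0("CPR:", 1:10)
EVALUATED_GROUPS <- c("CPR:3", "CPR:4", "CPR:5", "CPR:6", "CPR:9")
NEG_LABEL <- "NEG"
LABEL_SET <- c(EVALUATED_GROUPS, NEG_LABEL)
ENTITY_TYPES <- c("CHEMICAL", "GENE-Y", "GENE-N")

is_protein_type <- function(etype) etype %in% c("GENE-Y", "GENE-N")

#' Evaluated ChemProt relation groups
#'
#' The five CPR groups scored in the BioCreative VI ChemProt task
#' (CPR:3, CPR:4, CPR:5, CPR:6, CPR:9). All other groups are treated as
#' negatives by the candidate generator.
#'
#' @return Character vector of group names.
#' @export
evaluated_groups <- function() EVALUATED_GROUPS

#' Class labels of the sentence-level classifier
#'
#' @return The five evaluated CPR groups plus `"NEG"` (no evaluated relation),
#'   in the fixed order used for the softmax output and tie-breaking.
#' @export
cpi_labels <- function() LABEL_SET

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Equivalent to withr::with_seed but dependency-free
# so the installed package never needs withr at run time.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
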