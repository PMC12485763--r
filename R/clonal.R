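## Cross-sample analyses: methylated-haplotype switching across clones,
## presentation/relapse concordance, and per-sample allelic-block
## fraction. All of these assume the columns share one haplotype frame
## (a common phasing); the synthetic generator emits truth in a single
## frame, and real inputs must be synchronised upstream.

#' Build a clone-by-block state matrix
#'
#' Convenience: stacks per-sample state vectors (from
#' [classifyBlockState()]) into the blocks x samples matrix consumed by
#' [switchingSummary()]. `hapFlip` marks samples whose haplotype labels
#' are inverted relative to the common frame; their ASM states are
#' relabelled.
#'
#' @param stateList named list of per-sample state character vectors,
#'   all over the same blocks in the same order.
#' @param hapFlip logical vector (one per sample): flip hap1/hap2 labels.
#' @return character matrix, blocks x samples.
#' @export
cloneBlockMatrix <- function(stateList, hapFlip = NULL) {
  stopifnot(length(stateList) >= 1L)
  n <- unique(vapply(stateList, length, 1L))
  stopifnot(length(n) == 1L)
  if (is.null(hapFlip)) hapFlip <- rep(FALSE, length(stateList))
  stopifnot(length(hapFlip) == length(stateList))
  cols <- lapply(seq_along(stateList), function(j) {
    st <- stateList[[j]]
    if (hapFlip[j]) {
      st <- ifelse(st == "ASM_hap1_meth", "ASM_hap2_meth",
                   ifelse(st == "ASM_hap2_meth", "ASM_hap1_meth", st))
    }
    st
  })
  m <- do.call(cbind, cols)
  colnames(m) <- if (is.null(names(stateList)))
    paste0("sample", seq_along(stateList)) else names(stateList)
  m
}

.isASM <- function(state) state %in% c("ASM_hap1_meth", "ASM_hap2_meth")

#' Methylated-haplotype switching across clones
#'
#' Blocks with ASM in at least `minAsmSamples` columns are informative;
#' an informative block is concordant iff every ASM column has the same
#' methylated haplotype, otherwise switched. Switching is the signature
#' of random (rather than parent-of-origin) allele-specific methylation.
#'
#' @param stateMatrix blocks x samples character matrix of states in a
#'   common haplotype frame (see [cloneBlockMatrix()]).
#' @param minAsmSamples minimum clones with ASM for a block to count
#'   (default 4).
#' @return list: `n_informative_blocks`, `n_concordant`, `n_switched`,
#'   `switched_fraction`, and `per_block` (data.frame with the per-block
#'   ASM-clone count and outcome).
#' @export
switchingSummary <- function(stateMatrix, minAsmSamples = 4L) {
  stopifnot(is.matrix(stateMatrix))
  asm <- .isASM(stateMatrix)
  dim(asm) <- dim(stateMatrix)
  nAsm <- rowSums(asm)
  informative <- nAsm >= minAsmSamples
  outcome <- rep(NA_character_, nrow(stateMatrix))
  for (i in which(informative)) {
    haps <- stateMatrix[i, asm[i, ]]
    outcome[i] <- if (length(unique(haps)) == 1L) "concordant" else
      "switched"
  }
  nC <- sum(outcome == "concordant", na.rm = TRUE)
  nS <- sum(outcome == "switched", na.rm = TRUE)
  list(n_informative_blocks = sum(informative),
       n_concordant = nC, n_switched = nS,
       switched_fraction = if (sum(informative)) nS / sum(informative)
                           else NA_real_,
       per_block = data.frame(n_asm_clones = nAsm, outcome = outcome))
}

#' Concordance of block states between two timepoints
#'
#' Denominator: blocks with a significant call of the requested category
#' at both timepoints. ASM blocks are concordant iff the methylated
#' haplotype matches; epimutation blocks iff the direction
#' (hyper/hypo) matches.
#'
#' @param states1,states2 per-block state vectors (same blocks, same
#'   order, common haplotype frame).
#' @param category `"ASM"` or `"epimutation"`.
#' @return list: `n_blocks` (denominator), `n_concordant`,
#'   `concordance` fraction (`NA` when the denominator is empty).
#' @export
timepointConcordance <- function(states1, states2,
                                 category = c("ASM", "epimutation")) {
  category <- match.arg(category)
  stopifnot(length(states1) == length(states2))
  inCat <- if (category == "ASM") .isASM else
    function(s) s %in% c("hyper", "hypo")
  both <- inCat(states1) & inCat(states2)
  nC <- sum(states1[both] == states2[both])
  list(n_blocks = sum(both), n_concordant = nC,
       concordance = if (sum(both)) nC / sum(both) else NA_real_)
}

#' Fraction of a block universe with allelic methylation
#'
#' The allelic fraction is (ASM + hyper + hypo blocks) over the fixed
#' block universe; the fraction over evaluable blocks (states other
#' than `indeterminate`) is reported alongside.
#'
#' @param states per-block state vector over the full universe
#'   (indeterminate/inevaluable blocks included).
#' @param universeSize size of the block universe (defaults to
#'   `length(states)`).
#' @return list: `n_allelic`, `n_universe`, `fraction_universe`,
#'   `n_evaluable`, `fraction_evaluable`.
#' @export
allelicBlockFraction <- function(states, universeSize = length(states)) {
  stopifnot(universeSize >= 1L)
  allelic <- .isASM(states) | states %in% c("hyper", "hypo")
  evaluable <- states != "indeterminate"
  list(n_allelic = sum(allelic), n_universe = universeSize,
       fraction_universe = sum(allelic) / universeSize,
       n_evaluable = sum(evaluable),
       fraction_evaluable = if (sum(evaluable))
         sum(allelic) / sum(evaluable) else NA_real_)
}
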