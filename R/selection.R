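#' Build a trinucleotide-context opportunity model from coding sequences
#'
#' Enumerates every possible single-base substitution at every site of the
#' supplied in-frame coding sequences, labels each as synonymous or
#' non-synonymous from the codon table, and classifies it into the 96
#' pyrimidine-frame contexts. The resulting opportunity (L) matrix counts,
#' per context, how many distinct substitutions of each class the sequences
#' offer; totals are conserved at 3 substitutions per site. Sequence context
#' at the first and last base wraps around (sequences are treated as
#' circular for flanking purposes), so every site contributes a full
#' trinucleotide. Sequences whose frame contains a stop codon are excluded
#' with a warning.
#'
#' @param coding_sequences named character vector of in-frame sequences
#'   (lengths divisible by 3).
#' @return object of class `mseq_codingmodel`: list with `L` (96 x 2 matrix,
#'   columns `syn`/`nonsyn`), `substitutions` (enumeration data.frame) and
#'   `sequences`.
#' @export
build_opportunity <- function(coding_sequences) {
  if (length(coding_sequences) == 0L) stop_mseq("no coding sequences supplied")
  if (is.null(names(coding_sequences))) {
    names(coding_sequences) <- sprintf("cds%02d", seq_along(coding_sequences))
  }
  if (any(nchar(coding_sequences) %% 3L != 0L)) {
    stop_mseq("coding sequence lengths must be divisible by 3")
  }
  code <- Biostrings::GENETIC_CODE
  keep <- vapply(coding_sequences, function(s) {
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    !any(code[codons] == "*")
  }, logical(1))
  if (any(!keep)) {
    warning(sprintf("excluded %d stop-codon-containing sequence(s): %s",
                    sum(!keep),
                    paste(names(coding_sequences)[!keep], collapse = ", ")))
    coding_sequences <- coding_sequences[keep]
  }
  if (!length(coding_sequences)) stop_mseq("no valid coding sequences remain")

  subs <- lapply(names(coding_sequences), function(nm) {
    s <- coding_sequences[[nm]]
    L <- nchar(s)
    pos <- seq_len(L)
    base <- substring(s, pos, pos)
    fl5 <- substring(s, ifelse(pos == 1L, L, pos - 1L),
                     ifelse(pos == 1L, L, pos - 1L))
    fl3 <- substring(s, ifelse(pos == L, 1L, pos + 1L),
                     ifelse(pos == L, 1L, pos + 1L))
    off <- (pos - 1L) %% 3L
    codon_start <- pos - off
    codon <- substring(s, codon_start, codon_start + 2L)
    aa_ref <- unname(code[codon])
    ## three alternates per site
    rep3 <- function(x) rep(x, each = 3L)
    alt <- unlist(lapply(base, alt_bases), use.names = FALSE)
    codon3 <- rep3(codon)
    substr_pos <- rep3(off) + 1L
    alt_codon <- paste0(substr(codon3, 1L, substr_pos - 1L), alt,
                        substr(codon3, substr_pos + 1L, 3L))
    aa_alt <- unname(code[alt_codon])
    data.frame(
      seq = nm, pos = rep3(pos), ref = rep3(base), alt = alt,
      context96 = classify_context96(rep3(base), alt,
                                     paste0(rep3(fl5), rep3(base), rep3(fl3))),
      syn = aa_alt == rep3(aa_ref),
      stringsAsFactors = FALSE
    )
  })
  subs <- do.call(rbind, subs)
  labels <- context96_labels()
  L <- cbind(
    syn = as.numeric(table(factor(subs$context96[subs$syn], levels = labels))),
    nonsyn = as.numeric(table(factor(subs$context96[!subs$syn],
                                     levels = labels)))
  )
  rownames(L) <- labels
  structure(list(L = L, substitutions = subs, sequences = coding_sequences),
            class = "mseq_codingmodel")
}

#' Sample mutations from a neutral (or context-biased neutral) process
#'
#' Draws substitutions uniformly over the model's enumerated opportunities,
#' optionally reweighted per 96-context (a context-biased but still
#' selectively neutral process). Useful for calibration: under neutrality
#' the context-adjusted dN/dS tends to 1 regardless of context bias.
#'
#' @param model an `mseq_codingmodel`.
#' @param n number of mutations.
#' @param seed RNG seed.
#' @param context_weights optional named weights over the 96 contexts
#'   (relative mutation rates); default uniform.
#' @return data.frame sampled from `model$substitutions` (with replacement).
#' @export
simulate_neutral_mutations <- function(model, n, seed = 1L,
                                       context_weights = NULL) {
  stopifnot(inherits(model, "mseq_codingmodel"))
  subs <- model$substitutions
  w <- rep(1, nrow(subs))
  if (!is.null(context_weights)) {
    miss <- setdiff(unique(subs$context96), names(context_weights))
    cw <- stats::setNames(rep(1, 96L), context96_labels())
    cw[names(context_weights)] <- context_weights
    w <- cw[subs$context96]
  }
  with_seed(seed, {
    subs[sample.int(nrow(subs), n, replace = TRUE, prob = w), , drop = FALSE]
  })
}

#' Context-adjusted dN/dS per mutation compartment
#'
#' For each compartment (e.g. ubiquitous / shared / private), estimates the
#' non-synonymous/synonymous rate ratio `omega` by conditional maximum
#' likelihood under a 96-context Poisson rate model: within context `c`,
#' synonymous counts arise with rate `lambda_c * L_syn_c` and non-synonymous
#' counts with rate `omega * lambda_c * L_nonsyn_c`. Conditioning on the
#' per-context totals eliminates the nuisance rates `lambda_c` exactly, so
#' `n_nonsyn_c ~ Binomial(n_c, omega * L_nonsyn_c / (L_syn_c + omega *
#' L_nonsyn_c))` and `omega` is found by profile likelihood; the 95% CI is
#' the likelihood-ratio interval. Under a selectively neutral but
#' context-biased mutation process the estimate stays centred on 1, unlike
#' the naive count ratio (see [dnds_naive()]). Compartments without
#' synonymous mutations are flagged undefined.
#'
#' @param mutations data.frame with `context96`, `compartment` and either
#'   a logical `syn` column or a `consequence` column (synonymous vs other).
#' @param model an `mseq_codingmodel`.
#' @param conf confidence level.
#' @return data.frame (class `mseq_dnds`) with one row per compartment:
#'   `compartment`, `n_syn`, `n_nonsyn`, `ratio`, `ci_low`, `ci_high`,
#'   `note`.
#' @export
dnds <- function(mutations, model, conf = 0.95) {
  stopifnot(inherits(model, "mseq_codingmodel"))
  if (!"syn" %in% names(mutations)) {
    if (!"consequence" %in% names(mutations)) {
      stop_mseq("mutations need a syn or consequence column")
    }
    mutations$syn <- mutations$consequence == "synonymous"
  }
  if (!"compartment" %in% names(mutations)) mutations$compartment <- "all"
  labels <- rownames(model$L)
  out <- lapply(split(mutations, mutations$compartment), function(m) {
    comp <- m$compartment[1]
    n_syn_c <- as.numeric(table(factor(m$context96[m$syn], levels = labels)))
    n_non_c <- as.numeric(table(factor(m$context96[!m$syn], levels = labels)))
    n_syn <- sum(n_syn_c); n_nonsyn <- sum(n_non_c)
    if (n_syn == 0L) {
      return(data.frame(compartment = comp, n_syn = 0L, n_nonsyn = n_nonsyn,
                        ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, note = "undefined_no_synonymous",
                        stringsAsFactors = FALSE))
    }
    est <- omega_mle(n_non_c, n_syn_c, model$L[, "nonsyn"], model$L[, "syn"],
                     conf)
    data.frame(compartment = comp, n_syn = n_syn, n_nonsyn = n_nonsyn,
               ratio = est$omega, ci_low = est$ci[1], ci_high = est$ci[2],
               note = "", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("mseq_dnds", "data.frame")
  res
}

## Conditional profile likelihood of omega over contexts; lambda_c profiled
## out exactly by conditioning on per-context totals.
omega_mle <- function(n_non_c, n_syn_c, Ln, Ls, conf = 0.95) {
  use <- (n_non_c + n_syn_c) > 0 & (Ln + Ls) > 0
  y <- n_non_c[use]; x <- n_syn_c[use]
  ln <- Ln[use]; ls <- Ls[use]
  ll <- function(w) {
    p <- w * ln / (ls + w * ln)
    sum(y * log(ifelse(p > 0, p, 1)) + x * log(ifelse(p < 1, 1 - p, 1)))
  }
  if (sum(y) == 0) {
    w_hat <- 0; ll_max <- ll(0)
  } else {
    opt <- stats::optimize(function(lw) -ll(exp(lw)), c(-12, 12),
                           tol = 1e-10)
    w_hat <- exp(opt$minimum); ll_max <- -opt$objective
  }
  crit <- stats::qchisq(conf, df = 1L)
  dev <- function(w) 2 * (ll_max - ll(w)) - crit
  lo <- if (w_hat == 0 || dev(1e-9) < 0) 0 else {
    stats::uniroot(dev, c(1e-9, w_hat), tol = 1e-9)$root
  }
  hi <- if (dev(1e9) < 0) Inf else {
    stats::uniroot(dev, c(max(w_hat, 1e-9), 1e9), tol = 1e-9)$root
  }
  list(omega = w_hat, ci = c(lo, hi))
}

#' Naive (unadjusted) dN/dS
#'
#' The raw count ratio `(n_nonsyn / n_syn) / (L_nonsyn / L_syn)` without
#' context adjustment; biased under context-dependent mutation processes.
#' Provided for comparison with [dnds()].
#'
#' @param mutations as in [dnds()].
#' @param model an `mseq_codingmodel`.
#' @return data.frame with `compartment`, `ratio`.
#' @export
dnds_naive <- function(mutations, model) {
  if (!"syn" %in% names(mutations)) {
    mutations$syn <- mutations$consequence == "synonymous"
  }
  if (!"compartment" %in% names(mutations)) mutations$compartment <- "all"
  Lrat <- sum(model$L[, "nonsyn"]) / sum(model$L[, "syn"])
  out <- lapply(split(mutations, mutations$compartment), function(m) {
    data.frame(compartment = m$compartment[1],
               ratio = (sum(!m$syn) / max(1L, sum(m$syn))) / Lrat,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Random in-frame coding sequences for opportunity models
#'
#' Generates stop-free random coding sequences (rejection sampling per
#' codon), used to build toy opportunity models.
#'
#' @param n_seq number of sequences.
#' @param n_codons codons per sequence.
#' @param seed RNG seed.
#' @return named character vector.
#' @export
random_coding_sequences <- function(n_seq = 3L, n_codons = 500L, seed = 1L) {
  code <- Biostrings::GENETIC_CODE
  ok_codons <- names(code)[code != "*"]
  with_seed(seed, {
    out <- vapply(seq_len(n_seq), function(i) {
      paste(sample(ok_codons, n_codons, replace = TRUE), collapse = "")
    }, character(1))
    names(out) <- sprintf("cds%02d", seq_len(n_seq))
    out
  })
}
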