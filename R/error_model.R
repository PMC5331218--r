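#' Synthesis-error model configuration
#'
#' @param r Per-base synthesis error probability (0.01 for typical
#'   unpurified oligonucleotides).
#' @param phi Slowdown factor applied to strand-displacement reactions
#'   affected by a single synthesis error ("on the scale of 100-fold").
#' @param bm_len,toe_len Branch-migration / toehold domain lengths in nt.
#' @param single_error_policy `"slowdown"` (default: single-error molecules
#'   react at reduced rates per the domain rules) or `"inert"` (the
#'   phi -> infinity limit: single-error molecules do not react at all).
#' @return An `error_model_config` list.
#' @export
error_model_config <- function(r = 0.01, phi = 100, bm_len = 15, toe_len = 5,
                               single_error_policy = c("slowdown", "inert")) {
  stopifnot(r >= 0, r < 1, phi >= 1, bm_len > 0, toe_len > 0)
  structure(list(r = r, phi = phi, bm_len = bm_len, toe_len = toe_len,
                 single_error_policy = match.arg(single_error_policy)),
            class = "error_model_config")
}

#' Probability of n synthesis errors in an l-base strand
#'
#' Binomial model of stepwise chemical synthesis: each base independently
#' carries an error with probability `r`.
#'
#' @param l Strand length (nt).
#' @param n Error count.
#' @param r Per-base error probability.
#' @return `choose(l, n) r^n (1-r)^(l-n)`.
#' @export
#' @examples
#' error_prob(35, 0, 0.01) # ~0.703: error-free fraction of a signal strand
error_prob <- function(l, n, r) {
  stopifnot(l >= 0, all(n >= 0))
  if (any(n > l)) stop("error count n cannot exceed strand length l")
  dbinom(n, size = l, prob = r)
}

#' Probability of a signal strand's errors by domain
#'
#' Probability that a signal strand (two branch-migration domains flanking
#' a toehold) has exactly `s` errors in one specific branch-migration
#' domain (and none in the other) and `t` errors in the toehold.
#'
#' @param s Errors in the specific branch-migration domain.
#' @param t Errors in the toehold domain.
#' @param config An [error_model_config()] supplying `r` and the domain
#'   lengths.
#' @return The joint probability.
#' @export
domain_error_prob <- function(s, t, config = error_model_config()) {
  if (s > config$bm_len || t > config$toe_len || s < 0 || t < 0)
    stop("error counts out of range for the configured domain lengths")
  dbinom(s, config$bm_len, config$r) * dbinom(t, config$toe_len, config$r) *
    (1 - config$r)^config$bm_len
}

# Domain structure of a strand moiety, recognized by its id prefix.
# Signal strands: bm1 / toehold / bm2. Gate base strands: two toeholds
# flanking the recognition (branch migration) domain. Threshold bottom
# strands: extended-toehold recognition (two toehold-type segments) plus
# one bm domain; threshold top and reporter tops are bare bm domains.
moiety_domains <- function(moiety, config = error_model_config()) {
  b <- config$bm_len; t <- config$toe_len
  d <- if (startsWith(moiety, "s_")) {
    list(domain = c("bm1", "th", "bm2"), len = c(b, t, b),
         type = c("bm", "toe", "bm"))
  } else if (startsWith(moiety, "base_")) {
    list(domain = c("th1", "bm", "th2"), len = c(t, b, t),
         type = c("toe", "bm", "toe"))
  } else if (startsWith(moiety, "thb_")) {
    list(domain = c("ext", "th", "bm"), len = c(t, t, b),
         type = c("toe", "toe", "bm"))
  } else if (startsWith(moiety, "tht_") || startsWith(moiety, "rept_")) {
    list(domain = "bm", len = b, type = "bm")
  } else if (startsWith(moiety, "repb_")) {
    list(domain = c("th", "bm"), len = c(t, b), type = c("toe", "bm"))
  } else {
    stop("unknown strand moiety: ", moiety)
  }
  data.frame(domain = d$domain, len = d$len, type = d$type)
}

#' Partition a species into synthesis-error populations
#'
#' Splits one DNA species (a single strand, or a complex given as its
#' constituent strand moieties) into an error-free variant, one variant per
#' (strand, domain) carrying exactly one error, and an inert remainder
#' covering all molecules with more than one error. Complex fractions are
#' products over constituent strands.
#'
#' @param moieties Character vector of strand moiety ids (e.g. a signal
#'   strand `"s_1_2"`, or a gate:output complex
#'   `c("base_5", "s_5_7")`).
#' @param config An [error_model_config()].
#' @return Data frame with columns `variant` (`"ef"`,
#'   `"<moiety>.<domain>"`, `"inert"`), `moiety`, `domain`, `type` and
#'   `fraction`; fractions sum to 1.
#' @export
partition_species <- function(moieties, config = error_model_config()) {
  r <- config$r
  doms <- lapply(moieties, moiety_domains, config = config)
  lens <- vapply(doms, function(d) sum(d$len), numeric(1))
  p0 <- (1 - r)^lens # per-strand error-free probabilities
  rows <- list(data.frame(variant = "ef", moiety = NA_character_,
                          domain = NA_character_, type = NA_character_,
                          fraction = prod(p0)))
  for (i in seq_along(moieties)) {
    d <- doms[[i]]
    other <- prod(p0[-i])
    for (j in seq_len(nrow(d))) {
      # exactly one error, in this domain of this strand
      frac <- d$len[j] * r * (1 - r)^(lens[i] - 1) * other
      rows[[length(rows) + 1]] <- data.frame(
        variant = paste0(moieties[i], ".", d$domain[j]),
        moiety = moieties[i], domain = d$domain[j], type = d$type[j],
        fraction = frac)
    }
  }
  tab <- do.call(rbind, rows)
  inert <- 1 - sum(tab$fraction)
  rbind(tab, data.frame(variant = "inert", moiety = NA_character_,
                        domain = NA_character_, type = NA_character_,
                        fraction = inert))
}

# Species that no reaction consumes (threshold waste, triggered
# fluorophore, displaced quencher strands): never expanded — every variant
# flow lumps into the base species.
crn_sinks <- function(net) {
  consumed <- unique(c(net$reactions$r1, net$reactions$r2))
  setdiff(net$species$id, consumed[!is.na(consumed)])
}

#' Error populations for every species of a network
#'
#' @param net A `seesaw_crn`.
#' @param config An [error_model_config()].
#' @return Named list (per non-sink species) of [partition_species()]
#'   tables.
#' @export
error_populations <- function(net, config = error_model_config()) {
  ids <- setdiff(net$species$id, crn_sinks(net))
  setNames(lapply(ids, function(id)
    partition_species(net$composition[[id]], config)), ids)
}

variant_id <- function(id, variant) {
  if (variant == "ef") id else paste0(id, "~", variant)
}

#' Expand a purified network into the unpurified (synthesis-error) network
#'
#' Replaces every species by its error-population variants (initial
#' concentration = nominal x fraction) and instantiates every reaction
#' across reactive variant combinations. Rate rules: the base rate is kept
#' bit-for-bit when every participating strand is error-free; any
#' participating toehold-domain error divides the rate by `phi` for all
#' reaction types; a branch-migration-domain error divides the rate by
#' `phi` only in reversible, near-thermoneutral reactions (seesawing and
#' blunt-end leak exchange) and leaves irreversible thresholding/reporting
#' unchanged. Multi-error molecules are inert; variant combinations whose
#' products would carry more than one error are not instantiated (their
#' populations are second order in the single-error fractions), except
#' that terminal waste/fluorophore sinks absorb all variants.
#'
#' With `r = 0` the input network is returned unchanged, making the
#' purified model the exact zero-error limit.
#'
#' @param net A `seesaw_crn` built by [build_purified_crn()].
#' @param config An [error_model_config()].
#' @return The expanded `seesaw_crn`.
#' @export
expand_crn <- function(net, config = error_model_config()) {
  if (config$r == 0) return(net)
  phi <- config$phi
  krf_over_krs <- if (!is.null(net$rates))
    net$rates$k_rf / net$rates$k_rs else 20
  inert_policy <- config$single_error_policy == "inert"
  sinks <- crn_sinks(net)
  pops <- error_populations(net, config)

  sp <- net$species
  comp <- net$composition
  sp_rows <- list()
  known <- new.env(parent = emptyenv())
  add_variant_row <- function(vid, init, role, base_comp) {
    if (!is.null(known[[vid]])) return(invisible(NULL))
    known[[vid]] <- TRUE
    sp_rows[[length(sp_rows) + 1]] <<- data.frame(id = vid, init_x = init,
                                                  role = role)
    comp[[vid]] <<- base_comp
  }
  for (i in seq_len(nrow(sp))) {
    id <- sp$id[i]
    if (id %in% sinks) {
      add_variant_row(id, sp$init_x[i], sp$role[i], comp[[id]])
      next
    }
    pop <- pops[[id]]
    for (j in seq_len(nrow(pop))) {
      if (pop$variant[j] == "inert" && sp$init_x[i] == 0) next
      add_variant_row(variant_id(id, pop$variant[j]),
                      sp$init_x[i] * pop$fraction[j], sp$role[i], comp[[id]])
    }
  }

  rx <- net$reactions
  o_r1 <- o_r2 <- o_p1 <- o_p2 <- o_type <- character()
  o_rate <- numeric()
  for (q in seq_len(nrow(rx))) {
    reactants <- c(rx$r1[q], rx$r2[q]); reactants <- reactants[!is.na(reactants)]
    products <- c(rx$p1[q], rx$p2[q]); products <- products[!is.na(products)]
    vsets <- lapply(reactants, function(id) {
      pop <- pops[[id]]
      pop[pop$variant != "inert", , drop = FALSE]
    })
    combos <- as.matrix(expand.grid(lapply(vsets, function(v)
      seq_len(nrow(v)))))
    for (ci in seq_len(nrow(combos))) {
      errs <- NULL
      for (ri in seq_along(vsets)) {
        row <- vsets[[ri]][combos[ci, ri], ]
        if (row$variant != "ef") errs <- rbind(errs, row)
      }
      n_err <- if (is.null(errs)) 0L else nrow(errs)
      if (inert_policy && n_err > 0) next
      # map errors onto products by strand moiety
      pid <- character(length(products))
      ok <- TRUE
      for (pi in seq_along(products)) {
        p <- products[pi]
        if (p %in% sinks) { pid[pi] <- p; next }
        npe <- 0L; pv <- NULL
        if (n_err) {
          hit <- errs$moiety %in% net$composition[[p]]
          npe <- sum(hit)
          if (npe == 1) pv <- errs$variant[hit]
        }
        if (npe >= 2) { ok <- FALSE; break }
        pid[pi] <- if (npe == 1) variant_id(p, pv) else p
      }
      if (!ok) next
      rate <- rx$rate[q]
      if (n_err > 0) {
        if (rx$type[q] == "binding_off") {
          # a toehold error weakens binding: dissociation accelerates from
          # the slow to the fast unimolecular rate
          if (any(errs$type == "toe")) rate <- rate * krf_over_krs
        } else if (rx$type[q] != "binding_on") {
          slow <- any(errs$type == "toe") ||
            (any(errs$type == "bm") && rx$type[q] %in% c("seesawing", "leak"))
          if (slow) rate <- rate / phi
        }
      }
      rid <- vapply(seq_along(reactants), function(ri)
        variant_id(reactants[ri], vsets[[ri]]$variant[combos[ci, ri]]),
        character(1))
      # ensure product variant rows exist (dynamically formed species)
      for (pi in seq_along(products)) {
        if (!products[pi] %in% sinks)
          add_variant_row(pid[pi], 0,
                          sp$role[match(products[pi], sp$id)],
                          net$composition[[products[pi]]])
      }
      o_r1 <- c(o_r1, rid[1])
      o_r2 <- c(o_r2, if (length(rid) > 1) rid[2] else NA_character_)
      o_p1 <- c(o_p1, pid[1])
      o_p2 <- c(o_p2, if (length(pid) > 1) pid[2] else NA_character_)
      o_rate <- c(o_rate, rate)
      o_type <- c(o_type, rx$type[q])
    }
  }

  reactions <- data.frame(r1 = o_r1, r2 = o_r2, p1 = o_p1, p2 = o_p2,
                          rate = o_rate, type = o_type,
                          rev = rep(NA_integer_, length(o_r1)))
  expanded <- new_crn(do.call(rbind, sp_rows), reactions, comp,
                      net$std_conc_nM, net$circuit)
  expanded$error_config <- config
  expanded
}
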