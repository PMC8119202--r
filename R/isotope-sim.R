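#' Configuration of the [U-13C]-glucose label-propagation network
#'
#' Ground-truth parameters of an atom-mapped glycolysis/TCA model at isotopic
#' steady state. Fully labeled glucose yields M+3 pyruvate; pyruvate enters
#' the TCA cycle through pyruvate dehydrogenase (PDH, M+2 acetyl unit after
#' loss of C1 as CO2) with flux fraction `phi_pdh`, through pyruvate
#' carboxylase (PC, M+3 oxaloacetate with unlabeled CO2) with fraction
#' `phi_pc`, the remainder leaving as lactate. The oxaloacetate (OAA) pool
#' mixes PC influx, unlabeled anaplerotic influx and malate recycled through
#' full TCA turns.
#'
#' @param f_glc_labeled Fraction of glucose molecules fully 13C-labeled.
#' @param pyr_dilution Fraction of the pyruvate pool fed from unlabeled
#'   (non-glucose) sources.
#' @param phi_pdh,phi_pc Pyruvate-consuming flux fractions
#'   (`phi_pdh + phi_pc <= 1`). Unlabeled acetyl influx (e.g. beta-oxidation)
#'   and unlabeled anaplerosis make up the rest of each pool's influx, so the
#'   labeled share of the acetyl pool scales with `phi_pdh` and the PC-derived
#'   share of fresh OAA influx with `phi_pc`.
#' @param u_anaplerotic Fraction of fresh OAA influx that is obligatorily
#'   unlabeled (non-pyruvate anaplerosis); at 1 the PC branch contributes no
#'   label.
#' @param cycling_weight Fraction of the OAA pool regenerated through full
#'   TCA turns (vs fresh influx).
#' @param glu_exchange Fraction of the glutamate pool equilibrated with
#'   alpha-ketoglutarate.
#' @param tol Fixed-point convergence tolerance on the OAA distribution.
#' @param max_iters Iteration cap.
#' @param seed Seed (used by the Monte-Carlo oracle only).
#' @return A `"label_network_config"` list.
#' @export
label_network_config <- function(f_glc_labeled = 1, pyr_dilution = 0.1,
                                 phi_pdh = 0.6, phi_pc = 0.2,
                                 u_anaplerotic = 0.5, cycling_weight = 0.2,
                                 glu_exchange = 0.8, tol = 1e-10,
                                 max_iters = 1000L, seed = 1L) {
  fracs <- c(f_glc_labeled = f_glc_labeled, pyr_dilution = pyr_dilution,
             phi_pdh = phi_pdh, phi_pc = phi_pc,
             u_anaplerotic = u_anaplerotic, cycling_weight = cycling_weight,
             glu_exchange = glu_exchange)
  if (any(fracs < 0 | fracs > 1))
    stop("label_network_config: all fractions must lie in [0, 1]; offending: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (phi_pdh + phi_pc > 1 + 1e-12)
    stop("label_network_config: phi_pdh + phi_pc must be <= 1")
  stopifnot(tol > 0, max_iters >= 1)
  structure(c(as.list(fracs),
              list(tol = tol, max_iters = as.integer(max_iters),
                   seed = as.integer(seed))),
            class = "label_network_config")
}

# Stage probabilities shared by the solver and the Monte-Carlo oracle.
# Within-moiety carbon positions are treated as exchangeable: each
# decarboxylation removes a labeled carbon from the OAA-derived moiety with
# probability (labeled count)/(moiety size).
label_model <- function(config) {
  p <- config$f_glc_labeled * (1 - config$pyr_dilution)  # P(pyruvate M+3)
  list(
    p_pyr = p,
    p_acetyl2 = config$phi_pdh * p,                      # P(acetyl M+2)
    p_fresh3 = (1 - config$u_anaplerotic) * config$phi_pc * p  # P(fresh OAA M+3)
  )
}

# transition of the OAA-derived labeled count through one decarboxylation:
# from counts 0..size to 0..size-1 (loss probability b/size)
decarb_matrix <- function(size) {
  T <- matrix(0, size + 1L, size)
  for (b in 0:size) {
    if (b > 0) T[b + 1L, b] <- b / size          # labeled carbon lost
    if (b < size) T[b + 1L, b + 1L] <- 1 - b / size
  }
  T
}

# convolve the acetyl mass {0,2} with a moiety distribution
with_acetyl <- function(moiety, p_a2, total_len) {
  out <- numeric(total_len)
  out[seq_along(moiety)] <- out[seq_along(moiety)] + (1 - p_a2) * moiety
  out[seq_along(moiety) + 2L] <- out[seq_along(moiety) + 2L] + p_a2 * moiety
  out
}

#' Simulate steady-state mass-isotopolog distributions
#'
#' Solves the label network of a [label_network_config()] by fixed-point
#' iteration on the OAA labeled-carbon distribution: citrate is the acetyl
#' (x) OAA joint state; the two oxidative decarboxylations each remove a
#' carbon from the OAA-derived moiety (labeled with probability
#' labeled-count / moiety-size, the exchangeable-position approximation);
#' recycled malate re-enters the OAA mixture with weight `cycling_weight`.
#' Succinate symmetry is automatic at mass resolution.
#'
#' @param config A [label_network_config()].
#' @return Named list of [mid_profile()]s for pyruvate, lactate, citrate,
#'   akg (alpha-ketoglutarate), succinate, fumarate, malate, aspartate and
#'   glutamate, with attribute `"iterations"`.
#' @export
simulate_mids <- function(config) {
  stopifnot(inherits(config, "label_network_config"))
  mp <- label_model(config)
  fresh <- c(1 - mp$p_fresh3, 0, 0, mp$p_fresh3, 0)  # OAA counts 0..4
  T1 <- decarb_matrix(4L)   # OAA moiety in citrate: 4 carbons -> 3
  T2 <- decarb_matrix(3L)   # moiety in alpha-KG: 3 carbons -> 2

  oaa <- fresh
  last_res <- Inf
  for (it in seq_len(config$max_iters)) {
    b1 <- as.numeric(oaa %*% T1)            # moiety after first decarb, 0..3
    b2 <- as.numeric(b1 %*% T2)             # after second decarb, 0..2
    malate <- with_acetyl(b2, mp$p_acetyl2, 5L)  # malate mass 0..4
    oaa_new <- config$cycling_weight * malate +
      (1 - config$cycling_weight) * fresh
    res <- max(abs(oaa_new - oaa))
    oaa <- oaa_new
    if (res < config$tol) break
    last_res <- res
  }
  if (res >= config$tol)
    stop("simulate_mids: no convergence in ", config$max_iters,
         " iterations (residual ", format(res), ")")

  b1 <- as.numeric(oaa %*% T1)
  b2 <- as.numeric(b1 %*% T2)
  pyr <- c(1 - mp$p_pyr, 0, 0, mp$p_pyr)
  akg <- with_acetyl(b1, mp$p_acetyl2, 6L)
  succ <- with_acetyl(b2, mp$p_acetyl2, 5L)
  glu <- config$glu_exchange * akg
  glu[1] <- glu[1] + (1 - config$glu_exchange)

  out <- list(
    pyruvate = mid_profile("pyruvate", pyr),
    lactate = mid_profile("lactate", pyr),
    citrate = mid_profile("citrate", with_acetyl(oaa, mp$p_acetyl2, 7L)),
    akg = mid_profile("akg", akg),
    succinate = mid_profile("succinate", succ),
    fumarate = mid_profile("fumarate", succ),
    malate = mid_profile("malate", succ),
    aspartate = mid_profile("aspartate", oaa),
    glutamate = mid_profile("glutamate", glu))
  attr(out, "iterations") <- it
  out
}

#' Monte-Carlo oracle for the label network
#'
#' Samples individual molecules through the same atom maps as
#' [simulate_mids()] but by forward ancestry simulation, independent of the
#' fixed-point solver: each molecule's OAA moiety has a Geometric
#' (`1 - cycling_weight`) number of completed TCA turns behind it (capped at
#' depth 60), starting from a freshly sampled OAA and applying the
#' acetyl-condensation / double-decarboxylation turn that many times.
#'
#' @param config A [label_network_config()].
#' @param n_molecules Number of molecules to sample.
#' @param seed Seed; defaults to `config$seed`.
#' @return Named list of empirical [mid_profile()]s (same metabolites as
#'   [simulate_mids()]).
#' @export
mc_oracle <- function(config, n_molecules = 1e5, seed = NULL) {
  stopifnot(inherits(config, "label_network_config"), n_molecules >= 1)
  set.seed(seed %||% config$seed)
  n <- as.integer(n_molecules)
  mp <- label_model(config)
  cw <- min(config$cycling_weight, 1 - 1e-12)

  one_turn <- function(b) {
    a <- 2L * (stats::runif(length(b)) < mp$p_acetyl2)
    b1 <- b - (stats::runif(length(b)) < b / 4)
    b2 <- b1 - (stats::runif(length(b)) < b1 / 3)
    a + b2
  }

  G <- pmin(stats::rgeom(n, 1 - cw), 60L)
  b <- 3L * (stats::runif(n) < mp$p_fresh3)
  if (max(G) > 0) for (k in seq_len(max(G))) {
    act <- which(G >= k)
    b[act] <- one_turn(b[act])
  }
  # observed condensation and oxidative decarboxylations
  a <- 2L * (stats::runif(n) < mp$p_acetyl2)
  b1 <- b - (stats::runif(n) < b / 4)
  b2 <- b1 - (stats::runif(n) < b1 / 3)
  pyr <- 3L * (stats::runif(n) < mp$p_pyr)
  glu <- ifelse(stats::runif(n) < config$glu_exchange, a + b1, 0L)

  emp <- function(counts, n_carbons, name) {
    f <- tabulate(counts + 1L, nbins = n_carbons + 1L) / length(counts)
    mid_profile(name, f)
  }
  list(pyruvate = emp(pyr, 3L, "pyruvate"),
       lactate = emp(pyr, 3L, "lactate"),
       citrate = emp(a + b, 6L, "citrate"),
       akg = emp(a + b1, 5L, "akg"),
       succinate = emp(a + b2, 4L, "succinate"),
       fumarate = emp(a + b2, 4L, "fumarate"),
       malate = emp(a + b2, 4L, "malate"),
       aspartate = emp(b, 4L, "aspartate"),
       glutamate = emp(glu, 5L, "glutamate"))
}

#' Forward natural-abundance convolution
#'
#' Applies the same binomial natural-abundance / tracer-purity kernel as
#' [correction_matrix()] in the forward direction, turning a true MID into
#' the isotopolog spectrum an instrument would measure. Together with
#' [correct_natural_abundance()] this forms an exact round trip.
#'
#' @param mid A [mid_profile()].
#' @param p13_natural,tracer_purity Kernel parameters.
#' @param total Total intensity of the output spectrum (default 1).
#' @param protein_ug Protein annotation carried on the spectrum.
#' @return An [isotopolog_spectrum()].
#' @export
apply_natural_abundance <- function(mid, p13_natural = 0.0107,
                                    tracer_purity = 0.99, total = 1,
                                    protein_ug = 1) {
  stopifnot(inherits(mid, "mid_profile"))
  n <- length(mid$fractions) - 1L
  C <- correction_matrix(n, p13_natural, tracer_purity)
  meas <- as.numeric(C %*% mid$fractions)
  isotopolog_spectrum(mid$metabolite, n, meas / sum(meas) * total,
                      protein_ug = protein_ug)
}

#' First-turn closed-form citrate fractions
#'
#' With `cycling_weight = 0` the OAA pool equals the fresh influx and the
#' citrate MID has closed-form entries as products of the configuration
#' fractions: `M+2 = phi_pdh x p x (1 - q)`, `M+3 = (1 - phi_pdh x p) x q`
#' with `p = f_glc_labeled x (1 - pyr_dilution)` and
#' `q = (1 - u_anaplerotic) x phi_pc x p`. Used as an analytic cross-check
#' of the solver.
#'
#' @param config A [label_network_config()] (its `cycling_weight` is ignored;
#'   the formula assumes 0).
#' @return Named numeric: `m2`, `m3`, `m5` (acetyl + PC-OAA), `m0`.
#' @export
first_turn_citrate <- function(config) {
  mp <- label_model(config)
  a2 <- mp$p_acetyl2; q <- mp$p_fresh3
  c(m0 = (1 - a2) * (1 - q), m2 = a2 * (1 - q), m3 = (1 - a2) * q,
    m5 = a2 * q)
}
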