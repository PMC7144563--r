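#' Catalogue of synthetic QSPR descriptors
#'
#' The 47 descriptor labels used by the synthetic generator, grouped into
#' the families a steroid-permeability dataset would carry — lipophilicity
#' (logP/logD variants from several programs), aqueous solubility (logS
#' variants), molecular size (MW/volume/refractivity/polarizability/surface
#' areas), polarity (PSA variants, H-bond counts), integer structural
#' counts, and miscellaneous pharmacokinetic/physicochemical descriptors —
#' each with a free-text provenance tag naming the kind of software that
#' would supply it.
#'
#' The `axis` column records which latent axis of the generator the
#' descriptor tracks: `bulk` (molecular size and everything that follows it
#' — melting behavior, shape, flexibility, rotatable bonds, the structural
#' counts, and the jointly size-driven pharmacokinetic predictions such as
#' clearance, Caco2 permeability, absorption and CNS penetration), `lipsol`
#' (the lipophilicity-solubility axis: logP and logD variants load
#' positively, logS variants negatively, and the classically logP-driven
#' HLB, skin permeability and volume of distribution positively), or
#' `polarity` (PSA variants and hydrogen-bond counts).
#'
#' @return data.frame with columns `descriptor`, `family`, `axis`,
#'   `provenance`.
#' @export
descriptor_catalogue <- function() {
  fam <- function(names, family, axis, provenance)
    data.frame(descriptor = names, family = family, axis = axis,
               provenance = provenance, stringsAsFactors = FALSE)
  rbind(
    fam(c("1_cLogP", "2_logP", "3_logP", "4_LogP",
          "logD, pH 7.4", "logD, pH 5.5"), "lipophilicity", "lipsol",
        c("Data Warrior", "Marvin", "ACD/Labs", "pkCSM", "Marvin",
          "Marvin")),
    fam(c("1_cLogS", "2_logS", "3_logS"), "solubility", "lipsol",
        c("Data Warrior", "Marvin", "pkCSM")),
    fam(c("MW", "Molar Volume", "Molar Refractivity", "Refractivity index",
          "Polarizability", "Surface Area", "Total Surface Area"),
        "size", "bulk",
        c("pkCSM", "ACD/Labs", "ACD/Labs", "ACD/Labs", "ACD/Labs", "pkCSM",
          "Data Warrior")),
    fam(c("PSA", "Topological PSA", "Relative PSA",
          "H-Acceptors", "H-Donors"), "polarity", "polarity",
        c("ACD/Labs", "PubChem", "Data Warrior", "Data Warrior",
          "Data Warrior")),
    fam(c("Double bonds", "No of triple bonds", "Chlorine", "Fluoride",
          "Aromatic Rings", "Carboxyl group", "Carbonyl group",
          "Hydroxyl group", "No of Rings"), "structural", "bulk",
        c("pkCSM", "structure", "structure", "structure", "Data Warrior",
          "Data Warrior", "Data Warrior", "Data Warrior", "Marvin")),
    fam(c("exper_Melting Point", "cMelting Point", "pKa (Strongest Acidic)",
          "pKa (Strongest Basic)", "Shape Index", "Molecular Complexity",
          "Molecular Flexibility", "Drug-likeness", "Rotatable Bonds",
          "Total Clearance", "Caco2 Permeability", "Intestinal absorption",
          "log BB", "logPS"), "misc", "bulk",
        c("Open Melting Point Dataset", "EPA DSSTox", "Marvin", "Marvin",
          "Data Warrior", "Data Warrior", "Data Warrior", "Data Warrior",
          "pkCSM", "pkCSM", "pkCSM", "pkCSM", "pkCSM", "pkCSM")),
    fam(c("HLB", "log Kp", "VDss"), "misc", "lipsol",
        c("Marvin", "pkCSM", "pkCSM")))
}

#' Specification for a synthetic QSPR dataset
#'
#' Parameters of the generator. A low-rank latent structure drives both the
#' descriptor blocks and the response, so every downstream stage (scaling,
#' PLS, cross-validation, permutation testing, diagnostics) can be tested
#' against known ground truth. The default geometry emulates a 32-compound,
#' 47-descriptor steroid permeability table with three latent axes of
#' strongly graded descriptor support:
#' \describe{
#'   \item{bulk}{molecular size and its many followers — the dominant X
#'     block (26 descriptors including the integer structural counts);}
#'   \item{lipsol}{lipophilicity versus aqueous solubility — 12 descriptors,
#'     logS variants loading negatively;}
#'   \item{polarity}{PSA and hydrogen bonding — only 5 descriptors.}
#' }
#' The response weights run the other way (`signal_coefficients`
#' c(0.5, 0.75, 0.85) for bulk, lipsol, polarity): permeability depends
#' most on polarity and solubility and least on sheer size. This inverse
#' grading is what makes the dataset genuinely three-dimensional for PLS —
#' the dominant X direction is not the best predictor, so a well-chosen
#' model needs all three components, as real steroid-permeability models
#' do.
#'
#' @param n_obs number of compounds (default 32).
#' @param n_desc number of descriptors (default 47, drawn in catalogue
#'   order; values above 47 recycle the catalogue with suffixed names).
#' @param latent_rank number of latent axes (default 3; smaller values wrap
#'   the axis assignment).
#' @param signal_coefficients latent-to-response weights, length
#'   `latent_rank` (default `c(0.5, 0.75, 0.85)`).
#' @param noise_sd response noise standard deviation on the latent scale
#'   (default 0.05, a strong signal: true R-squared above 0.99).
#' @param block_correlations named within-family |correlation| targets for
#'   the size, lipophilicity, solubility and polarity families (defaults
#'   0.94, 0.81, 0.81, 0.90); misc descriptors inherit the target of the
#'   family sharing their axis, structural counts use a fixed loading of
#'   0.6 before discretization.
#' @param response_center,response_scale affine map from the latent-scale
#'   response to permeability units (cm/h); defaults 0.03 and 0.005.
#' @param seed integer seed; the same spec and seed reproduce the dataset
#'   bit for bit.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_obs = 32L, n_desc = 47L, latent_rank = 3L,
                           signal_coefficients = c(0.5, 0.75, 0.85),
                           noise_sd = 0.05,
                           block_correlations = c(size = 0.94,
                                                  lipophilicity = 0.81,
                                                  solubility = 0.81,
                                                  polarity = 0.90),
                           response_center = 0.03, response_scale = 0.005,
                           seed = 1L) {
  if (latent_rank > min(n_obs, n_desc))
    stop("latent rank exceeds min(n_obs, n_desc)", call. = FALSE)
  if (latent_rank < 1L) stop("latent rank must be >= 1", call. = FALSE)
  if (length(signal_coefficients) != latent_rank)
    stop("need one signal coefficient per latent factor", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  need <- c("size", "lipophilicity", "solubility", "polarity")
  if (!all(need %in% names(block_correlations)))
    stop("block_correlations must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(block_correlations <= 0 | block_correlations >= 1))
    stop("block correlation targets must lie in (0, 1)", call. = FALSE)
  structure(list(n_obs = as.integer(n_obs), n_desc = as.integer(n_desc),
                 latent_rank = as.integer(latent_rank),
                 signal_coefficients = signal_coefficients,
                 noise_sd = noise_sd,
                 block_correlations = block_correlations,
                 response_center = response_center,
                 response_scale = response_scale,
                 seed = as.integer(seed)), class = "synthetic_spec")
}

# latent axis index per catalogue axis label, wrapping if latent_rank < 3
axis_factor <- function(axis, rank) {
  base <- c(bulk = 1L, lipsol = 2L, polarity = 3L)
  ((base[axis] - 1L) %% rank) + 1L
}

# plausible location/scale per family so raw tables read like real data
family_affine <- function(family) {
  switch(family,
         lipophilicity = c(center = 2.2, scale = 1.1),
         solubility = c(center = -4.2, scale = 0.9),
         size = c(center = 330, scale = 55),
         polarity = c(center = 75, scale = 18),
         misc = c(center = 50, scale = 20),
         c(center = 0, scale = 1))
}

# loading of descriptor j on its latent axis: sqrt of the block correlation
# target of the family anchoring that axis; logS variants load negatively
descriptor_loading <- function(family, axis, targets) {
  lam <- switch(axis,
                bulk = sqrt(targets[["size"]]),
                lipsol = sqrt(targets[["lipophilicity"]]),
                polarity = sqrt(targets[["polarity"]]))
  if (family == "solubility") lam <- -sqrt(targets[["solubility"]])
  if (family == "structural") lam <- 0.6
  lam
}

generate_X <- function(spec) {
  cat47 <- descriptor_catalogue()
  reps <- ceiling(spec$n_desc / nrow(cat47))
  cat_full <- do.call(rbind, lapply(seq_len(reps), function(r) {
    d <- cat47
    if (r > 1L) d$descriptor <- paste0(d$descriptor, " (", r, ")")
    d
  }))[seq_len(spec$n_desc), , drop = FALSE]
  n <- spec$n_obs
  r <- spec$latent_rank
  L <- matrix(stats::rnorm(n * r), n, r)
  X <- matrix(0, n, spec$n_desc)
  loadings <- matrix(0, spec$n_desc, r)
  for (j in seq_len(spec$n_desc)) {
    family <- cat_full$family[j]
    k <- axis_factor(cat_full$axis[j], r)
    lam <- descriptor_loading(family, cat_full$axis[j],
                              spec$block_correlations)
    z <- lam * L[, k] + sqrt(1 - lam^2) * stats::rnorm(n)
    loadings[j, k] <- lam
    if (family == "structural") {
      # thresholded latent normal -> counts in {0, 1, 2}
      X[, j] <- (z > 0) + (z > stats::qnorm(0.85))
    } else {
      aff <- family_affine(family)
      X[, j] <- aff[["center"]] + aff[["scale"]] * z
    }
  }
  ids <- sprintf("COMP %d", seq_len(n))
  dimnames(X) <- list(ids, cat_full$descriptor)
  dimnames(loadings) <- list(cat_full$descriptor,
                             paste0("factor", seq_len(r)))
  list(X = X, L = L, loadings = loadings,
       provenance = cat_full$provenance)
}

#' Generate a synthetic QSPR dataset with known ground truth
#'
#' Draws latent axis scores, builds correlated descriptor blocks from them,
#' and forms the response as a linear combination of the axes plus Gaussian
#' noise, affinely mapped to permeability units. The returned ground truth
#' (latent scores, block loadings, coefficients, true R-squared) supports
#' full parameter-recovery testing of the modelling and validation stages.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `table` ([descriptor_table]), `response`
#'   ([response_block], name "P_app"), `ground_truth` (list with `latent`,
#'   `loadings`, `signal_coefficients`, `noise_sd`, `true_R2`, `y_latent`).
#' @export
generate_qspr <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  gx <- generate_X(spec)
  signal <- as.numeric(gx$L %*% spec$signal_coefficients)
  noise <- stats::rnorm(spec$n_obs, sd = spec$noise_sd)
  y_lat <- signal + noise
  y <- spec$response_center + spec$response_scale * y_lat
  true_r2 <- sum(spec$signal_coefficients^2) /
    (sum(spec$signal_coefficients^2) + spec$noise_sd^2)
  list(table = descriptor_table(gx$X, provenance = gx$provenance),
       response = response_block(y, ids = rownames(gx$X), name = "P_app",
                                 check_nonneg = FALSE),
       ground_truth = list(latent = gx$L, loadings = gx$loadings,
                           signal_coefficients = spec$signal_coefficients,
                           noise_sd = spec$noise_sd, true_R2 = true_r2,
                           y_latent = y_lat))
}

#' Generate a null dataset (response independent of X)
#'
#' Same descriptor structure as [generate_qspr()], but the response is pure
#' independent noise — the calibration case for cross-validated Q-squared
#' and permutation validation under the null.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `table` and `response` (name "y_null").
#' @export
generate_null <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  gx <- generate_X(spec)
  y <- spec$response_center +
    spec$response_scale * stats::rnorm(spec$n_obs)
  list(table = descriptor_table(gx$X, provenance = gx$provenance),
       response = response_block(y, ids = rownames(gx$X), name = "y_null",
                                 check_nonneg = FALSE))
}

#' Generate a Franz-cell series from a known permeability
#'
#' Inverts the cumulative-amount bookkeeping: the corrected cumulative
#' amount per area is built exactly linear with slope
#' \eqn{J_{ss} = P_{app} C_d} (after an optional lag), receptor
#' concentrations are solved recursively from it, and multiplicative noise
#' of coefficient of variation `noise_cv` is applied last. With
#' `noise_cv = 0` the downstream reduction recovers `true_P_app` exactly.
#'
#' @param true_P_app ground-truth apparent permeability (cm/h).
#' @param times sampling times in hours (default 0.5, 1, 2, 4, 6, 8).
#' @param donor_concentration,area,receptor_volume,sample_volume cell
#'   geometry; defaults 100 ug/mL, 4.9 cm^2, 20 mL, 0.5 mL.
#' @param lag lag time (h) before the linear rise starts (default 0).
#' @param noise_cv multiplicative noise sd on concentrations (default 0).
#' @param seed optional seed for the noise draw.
#' @param compound,replicate_id labels.
#' @return A [permeation_series].
#' @export
generate_permeation <- function(true_P_app, times = c(0.5, 1, 2, 4, 6, 8),
                                donor_concentration = 100, area = 4.9,
                                receptor_volume = 20, sample_volume = 0.5,
                                lag = 0, noise_cv = 0, seed = NULL,
                                compound = "synthetic",
                                replicate_id = "r1") {
  if (true_P_app < 0) stop("true_P_app must be >= 0", call. = FALSE)
  J <- true_P_app * donor_concentration
  Q <- J * pmax(times - lag, 0)
  C <- numeric(length(Q))
  prior <- 0
  for (i in seq_along(Q)) {
    C[i] <- (area * Q[i] - sample_volume * prior) / receptor_volume
    prior <- prior + C[i]
  }
  if (any(C < 0)) stop("geometry yields negative concentrations",
                       call. = FALSE)
  if (noise_cv > 0) {
    C <- with_seed(seed, C * (1 + stats::rnorm(length(C), sd = noise_cv)))
    C <- pmax(C, 0)
  }
  permeation_series(times, C, donor_concentration = donor_concentration,
                    area = area, receptor_volume = receptor_volume,
                    sample_volume = sample_volume, compound = compound,
                    replicate_id = replicate_id)
}

#' Write a synthetic dataset and its ground truth to disk
#'
#' Emits the CSV dialect [read_dataset()] consumes plus a JSON ground-truth
#' sidecar (`<stem>_truth.json`).
#'
#' @param spec a [synthetic_spec()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_synthetic_qspr <- function(spec, path) {
  g <- generate_qspr(spec)
  write_dataset(g$table, g$response, path)
  truth <- list(seed = spec$seed, n_obs = spec$n_obs, n_desc = spec$n_desc,
                latent_rank = spec$latent_rank,
                signal_coefficients = spec$signal_coefficients,
                noise_sd = spec$noise_sd,
                true_R2 = g$ground_truth$true_R2,
                y_latent = g$ground_truth$y_latent)
  jsonlite::write_json(truth, sub("\\.csv$", "_truth.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
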