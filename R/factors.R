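#' Questionnaire item inventory
#'
#' The 209 items of the nine-instrument battery: AUDIT (10), AES (18), SDS
#' (20), EAT-26 (26), BIS (30), OCI-R (18), STAI-trait (20), schizotypy
#' short scales (43) and LSAS (24).
#'
#' @return A tibble: `item` (label like `"OCIR_03"`), `instrument`.
#' @export
questionnaire_items <- function() {
  counts <- c(
    AUDIT = 10L, AES = 18L, SDS = 20L, EAT26 = 26L, BIS = 30L,
    OCIR = 18L, STAI_T = 20L, SCZ = 43L, LSAS = 24L
  )
  tibble::tibble(
    instrument = rep(names(counts), counts),
    item = unlist(lapply(names(counts), function(q) {
      sprintf("%s_%02d", q, seq_len(counts[[q]]))
    }))
  )[, c("item", "instrument")]
}

fixture_factor_of_instrument <- function(instrument) {
  # crude instrument -> primary-factor assignment for the synthetic fixture:
  # mood/anxiety scales to AD, compulsivity-spectrum scales to CIT,
  # social/apathy scales to SW
  c(
    AUDIT = "cit", AES = "sw", SDS = "ad", EAT26 = "cit", BIS = "cit",
    OCIR = "cit", STAI_T = "ad", SCZ = "cit", LSAS = "sw"
  )[instrument]
}

#' Synthetic factor-weight fixture
#'
#' Generates a 209 x 3 weight matrix for testing the scoring pipeline. The
#' true published weights are external data and are not shipped; this
#' fixture assigns each item a single primary-factor loading so that factor
#' scores computed from items simulated with
#' [simulate_item_responses()] show the moderate inter-correlations
#' (0.34--0.52) expected of the real dimensions.
#'
#' @param seed Integer seed.
#' @return A tibble: `item`, `ad`, `cit`, `sw`.
#' @export
make_weight_fixture <- function(seed = 1L) {
  set.seed(seed)
  inv <- questionnaire_items()
  primary <- fixture_factor_of_instrument(inv$instrument)
  w <- matrix(0, nrow(inv), 3, dimnames = list(NULL, c("ad", "cit", "sw")))
  loading <- stats::runif(nrow(inv), 0.6, 1.0)
  w[cbind(seq_len(nrow(inv)), match(primary, colnames(w)))] <- loading
  dplyr::bind_cols(tibble::tibble(item = inv$item), tibble::as_tibble(w))
}

#' Simulate questionnaire item responses
#'
#' Latent factor scores are drawn from a multivariate normal with the given
#' correlations (by default inflated relative to the dimension-score
#' defaults to offset the attenuation from item noise and 5-point
#' discretisation, so that induced factor-score correlations land in the
#' 0.34--0.52 band); each item is its primary factor times its fixture
#' loading plus unit noise, discretised onto a 0--4 integer scale.
#'
#' @param n_subjects Number of subjects.
#' @param weights Weight fixture from [make_weight_fixture()] (loadings are
#'   reused as generative loadings).
#' @param factor_corr 3x3 latent factor correlation matrix.
#' @param seed Integer seed.
#' @return A tibble: `subject` plus one integer column per item.
#' @export
simulate_item_responses <- function(n_subjects,
                                    weights = make_weight_fixture(),
                                    factor_corr = default_dimension_correlations(
                                      r_ad_cit = 0.52, r_ad_sw = 0.46, r_cit_sw = 0.38
                                    ),
                                    seed = 1L) {
  set.seed(seed)
  ch <- chol(factor_corr)
  f <- matrix(stats::rnorm(n_subjects * 3), n_subjects, 3) %*% ch
  colnames(f) <- c("ad", "cit", "sw")
  wm <- as.matrix(weights[, c("ad", "cit", "sw")])
  latent <- f %*% t(wm) +
    matrix(stats::rnorm(n_subjects * nrow(weights)), n_subjects)
  # map the continuous latent item onto a 5-point scale
  responses <- pmin(pmax(round(latent + 2), 0), 4)
  out <- tibble::as_tibble(responses, .name_repair = "minimal")
  names(out) <- weights$item
  dplyr::bind_cols(tibble::tibble(subject = seq_len(n_subjects)), out)
}

#' Score questionnaire items into transdiagnostic dimensions
#'
#' Column-standardises the item responses and multiplies by the weight
#' matrix, joining on item labels (column order is irrelevant). The item
#' transformation is an assumption of this implementation: standardisation
#' is the conventional pre-step for weighted factor scoring and makes the
#' scores scale-free.
#'
#' @param items Data frame of item responses: optional `subject` column plus
#'   one column per item, labelled as in the weight table.
#' @param weights Data frame: `item` plus numeric columns `ad`, `cit`, `sw`.
#' @return A tibble: `subject`, `ad`, `cit`, `sw`.
#' @examples
#' w <- make_weight_fixture(seed = 2)
#' items <- simulate_item_responses(200, w, seed = 3)
#' scores <- score_factors(items, w)
#' cor(scores[, c("ad", "cit", "sw")])
#' @export
score_factors <- function(items, weights) {
  stopifnot(all(c("item", "ad", "cit", "sw") %in% names(weights)))
  subject <- if ("subject" %in% names(items)) items$subject else seq_len(nrow(items))
  item_cols <- setdiff(names(items), "subject")
  missing_items <- setdiff(weights$item, item_cols)
  extra_items <- setdiff(item_cols, weights$item)
  if (length(missing_items) > 0 || length(extra_items) > 0) {
    stop(
      "item/weight label mismatch",
      if (length(missing_items) > 0) {
        paste0("; missing from items: ",
               paste(utils::head(missing_items, 5), collapse = ", "),
               if (length(missing_items) > 5) ", ...")
      },
      if (length(extra_items) > 0) {
        paste0("; unknown items: ",
               paste(utils::head(extra_items, 5), collapse = ", "),
               if (length(extra_items) > 5) ", ...")
      },
      call. = FALSE
    )
  }
  x <- as.matrix(items[, weights$item, drop = FALSE])
  if (anyNA(x)) stop("item responses contain missing values", call. = FALSE)
  xs <- scale(x)
  # items answered identically by everyone carry no signal
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  wm <- as.matrix(weights[, c("ad", "cit", "sw")])
  s <- xs %*% wm
  tibble::tibble(subject = subject, ad = s[, 1], cit = s[, 2], sw = s[, 3])
}
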