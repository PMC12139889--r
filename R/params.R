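# Model parameters, named presets, and preset config files.

#' Model parameters for the fission-fusion oscillator
#'
#' Bundles the four dimensionless constants of the Oregonator-type model of
#' mitochondrial dynamics: `epsilon`, the time scale of the fission factor
#' (DRP1); `epsilon_prime`, the (much faster) time scale of the intermediary
#' factor (MiD49/51); `q`, a rate constant; and `f`, the stoichiometric
#' feedback factor governing fusion-factor production. `f` is the knob used
#' to emulate disease (`f = 0.6`) and therapeutic intervention (`f = 1.2`).
#'
#' @param epsilon Positive time-scale parameter of the fission variable.
#' @param epsilon_prime Positive time-scale parameter of the intermediary
#'   variable. Much smaller than `epsilon` in all named presets, which is
#'   what makes the system stiff and the oscillations relaxation-like.
#' @param q Positive rate constant.
#' @param f Positive stoichiometric feedback factor.
#' @return An object of class `mito_params`: a named list with the four
#'   fields, validated strictly positive and finite.
#' @examples
#' mito_params(0.01, 0.001, 0.01, 1)
#' preset_params("normal")
#' @export
mito_params <- function(epsilon, epsilon_prime, q, f) {
  p <- list(
    epsilon = as.numeric(epsilon),
    epsilon_prime = as.numeric(epsilon_prime),
    q = as.numeric(q),
    f = as.numeric(f)
  )
  validate_params(p)
  structure(p, class = "mito_params")
}

validate_params <- function(p) {
  vals <- unlist(p[c("epsilon", "epsilon_prime", "q", "f")])
  if (length(vals) != 4L || anyNA(vals) || any(!is.finite(vals))) {
    rlang::abort("all four model parameters must be finite numbers",
                 class = "mitodyn_error_invalid_input")
  }
  if (any(vals <= 0)) {
    rlang::abort(
      "model parameters epsilon, epsilon_prime, q and f must be strictly positive",
      class = "mitodyn_error_invalid_input"
    )
  }
  invisible(p)
}

#' @export
print.mito_params <- function(x, ...) {
  cat(sprintf(
    "<mito_params> epsilon = %g, epsilon_prime = %g, q = %g, f = %g\n",
    x$epsilon, x$epsilon_prime, x$q, x$f
  ))
  invisible(x)
}

# The four printed parameter regimes.
.preset_table <- function() {
  tibble::tribble(
    ~preset,      ~epsilon, ~epsilon_prime, ~q,      ~f,
    "oregonator", 3.6e-2,   1.2e-4,         2.4e-4,  1,
    "normal",     0.01,     0.001,          0.01,    1,
    "diseased",   0.005,    0.0005,         0.02,    0.6,
    "therapy",    0.005,    0.0005,         0.02,    1.2
  )
}

#' Named parameter presets
#'
#' The four parameter regimes of the model: the classical Oregonator scaling
#' of the Belousov-Zhabotinsky reaction, and the normal, diseased
#' (cancer-like, reduced feedback `f`) and therapy (restored feedback)
#' regimes of the mitochondrial mapping.
#'
#' @return A tibble with columns `preset`, `epsilon`, `epsilon_prime`, `q`,
#'   `f`, one row per regime.
#' @export
mito_presets <- function() {
  .preset_table()
}

#' Look up one preset as a `mito_params` object
#'
#' @param name Preset name, one of `"oregonator"`, `"normal"`, `"diseased"`,
#'   `"therapy"` (case-insensitive).
#' @param presets Preset table to look in; defaults to [mito_presets()].
#'   Supply the result of [read_presets_config()] to use presets from file.
#' @return A [mito_params()] object.
#' @export
preset_params <- function(name, presets = mito_presets()) {
  if (!is.character(name) || length(name) != 1L) {
    rlang::abort("preset name must be a single string",
                 class = "mitodyn_error_invalid_input")
  }
  key <- tolower(trimws(name))
  row <- presets[tolower(presets$preset) == key, ]
  if (nrow(row) != 1L) {
    rlang::abort(
      sprintf("unknown preset '%s' (available: %s)", name,
              paste(presets$preset, collapse = ", ")),
      class = "mitodyn_error_invalid_input"
    )
  }
  mito_params(row$epsilon, row$epsilon_prime, row$q, row$f)
}

#' Read or write parameter presets as a plain-text config file
#'
#' The format is YAML with one block per regime, e.g.
#' ```yaml
#' normal:
#'   epsilon: 0.01
#'   epsilon_prime: 0.001
#'   q: 0.01
#'   f: 1
#' ```
#' Preset names are case-insensitive on lookup; each block must carry all
#' four parameter keys and pass [mito_params()] validation.
#'
#' @param path File path.
#' @return For the reader, a tibble shaped like [mito_presets()].
#' @export
read_presets_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)) || any(names(cfg) == "")) {
    rlang::abort("preset config must contain named regime blocks",
                 class = "mitodyn_error_invalid_input")
  }
  purrr::imap_dfr(cfg, function(block, nm) {
    p <- mito_params(block$epsilon, block$epsilon_prime, block$q, block$f)
    tibble::tibble(preset = tolower(nm), epsilon = p$epsilon,
                   epsilon_prime = p$epsilon_prime, q = p$q, f = p$f)
  })
}

#' @rdname read_presets_config
#' @param presets A preset tibble shaped like [mito_presets()].
#' @export
write_presets_config <- function(presets, path) {
  blocks <- purrr::map(seq_len(nrow(presets)), function(i) {
    as.list(presets[i, c("epsilon", "epsilon_prime", "q", "f")])
  })
  names(blocks) <- presets$preset
  yaml::write_yaml(blocks, path, precision = 15L)
  invisible(path)
}

#' Variable naming conventions
#'
#' The model's state variables and their biological aliases: `x` is the
#' fission factor (DRP1, the activator), `y` the intermediary factor
#' (MiD49/51, the adaptor pool recruiting DRP1), `z` the fusion factor
#' (MFN1/2 and OPA1, the delayed negative feedback).
#'
#' @return A tibble with columns `variable`, `alias`, `role`, `label`.
#' @export
variable_labels <- function() {
  tibble::tribble(
    ~variable, ~alias,          ~role,          ~label,
    "x",       "DRP1",          "fission",      "fission factor x (DRP1)",
    "y",       "MiD49/51",      "intermediary", "intermediary factor y (MiD49/51)",
    "z",       "MFN1/2-OPA1",   "fusion",       "fusion factor z (MFN1/2, OPA1)"
  )
}
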