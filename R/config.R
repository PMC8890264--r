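# Run configuration files ----------------------------------------------------

#' Read a run configuration file
#'
#' A YAML file with optional sections `model`, `train`, `weights` and
#' `fit`, whose keys are the arguments of [model_config()],
#' [train_config()], [loss_weights()] and [fit_config()] respectively.
#' Unknown keys are rejected so typos do not silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @return List with `model`, `train`, `weights`, `fit` objects (defaults
#'   where a section is absent).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(section, ctor) {
    args <- cfg[[section]]
    if (is.null(args)) return(ctor())
    known <- names(formals(ctor))
    bad <- setdiff(names(args), known)
    if (length(bad)) {
      stop("unknown ", section, " config keys: ", paste(bad, collapse = ", "))
    }
    do.call(ctor, args)
  }
  list(model = build("model", model_config),
       train = build("train", train_config),
       weights = build("weights", loss_weights),
       fit = build("fit", fit_config))
}

#' Write a run configuration file
#'
#' @param model,train,weights,fit Configuration objects to serialize.
#' @param path Output YAML path.
#' @export
write_run_config <- function(path, model = model_config(),
                             train = train_config(),
                             weights = loss_weights(), fit = fit_config()) {
  yaml::write_yaml(list(model = unclass(model), train = unclass(train),
                        weights = unclass(weights), fit = unclass(fit)),
                   path)
  invisible(path)
}
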