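#' Serialize and restore models as JSON
#'
#' Model specification files use the conventional bundle-analysis shorthand keys (`AE`, `VE`,
#' `EH`, `VH`, `ES`, `VS`, `EL`, `VL`, `ET`, `ST`, `Ca`, `Cb`, `a`, `b`,
#' `c`, `u0`).  A composite serializes as
#' `{"type":"composite","components":[{"kind":"E","weight":...,...},...]}`,
#' a series as `{"type":"series","components":[...]}`, and a single bundle
#' as `{"type":"bundle",...}`.
#'
#' @param model a [bundle_spec()], [composite_model()] or [series_model()].
#' @param path optional file; when given the JSON is written there.
#' @return `model_to_json` returns the JSON string invisibly when `path` is
#'   given; `model_from_json` returns the restored model object.
#' @export
model_to_json <- function(model, path = NULL) {
  bundle_rec <- function(sp, weight = NULL) {
    rec <- list(kind = sp$kind, a = sp$char$a, b = sp$char$b, c = sp$char$c,
                AE = sp$AE, VE = sp$VE)
    if (!is.null(weight)) rec$weight <- weight
    if (sp$kind == "EH") rec <- c(rec, list(EH = sp$EH, VH = sp$VH))
    if (sp$kind == "ES") rec <- c(rec, list(ES = sp$ES, VS = sp$VS,
                                            EL = sp$EL, VL = sp$VL))
    if (sp$kind == "ET") rec <- c(rec, list(ET = sp$ET, ST = sp$ST,
                                            Ca = sp$Ca, Cb = sp$Cb))
    if (sp$u0 != 0) rec$u0 <- sp$u0
    rec
  }
  obj <- if (inherits(model, "fbc_composite")) {
    list(type = "composite",
         components = Map(bundle_rec, model$components,
                          as.list(model$weights)),
         normalization = model$norm)
  } else if (inherits(model, "fbc_series")) {
    list(type = "series",
         components = lapply(seq_along(model$w), function(i) {
           list(weight = model$w[i], a = model$a[i], b = model$b[i],
                c = model$c[i], m = model$m[i], s = model$s[i],
                u0 = model$u0[i])
         }),
         units = model$units)
  } else if (inherits(model, "fbc_bundle")) {
    c(list(type = "bundle"), bundle_rec(model))
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname model_to_json
#' @param json JSON string or path to a JSON file.
#' @export
model_from_json <- function(json) {
  if (length(json) == 1 && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  restore_bundle <- function(rec) {
    g <- function(nm, def) if (!is.null(rec[[nm]])) rec[[nm]] else def
    bundle_spec(rec$kind,
                fbc_characteristic(rec$a, rec$b, rec$c),
                AE = rec$AE, VE = rec$VE,
                EH = g("EH", 0), VH = g("VH", 0),
                ES = rec$ES, VS = g("VS", 0),
                EL = rec$EL, VL = g("VL", 0),
                ET = g("ET", 0), ST = g("ST", 0),
                Ca = g("Ca", 0), Cb = g("Cb", 0), u0 = g("u0", 0))
  }
  switch(obj$type,
    bundle = restore_bundle(obj),
    composite = {
      comps <- lapply(obj$components, restore_bundle)
      w <- vapply(obj$components, `[[`, 0, "weight")
      composite_model(comps, weights = w, norm = obj$normalization)
    },
    series = {
      f <- function(nm) vapply(obj$components, function(r) {
        v <- r[[nm]]; if (is.null(v)) 0 else v
      }, 0)
      series_model(w = f("weight"), a = f("a"), b = f("b"), c = f("c"),
                   m = f("m"), s = f("s"), u0 = f("u0"), units = obj$units)
    },
    stop("unknown model type: ", obj$type, call. = FALSE))
}
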