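#' @title WikiPathways web-service client
#' @description Queries and downloads pathways from a WikiPathways-style
#'   REST service with an explicit cancellation contract: every operation
#'   takes a cancellation token that can be set from outside the running
#'   request; once set it stays set, a pre-cancelled token prevents any
#'   network traffic, and a token set mid-transfer aborts the request
#'   within one polling interval, leaving no partial results (including no
#'   partial cache entries). The transport layer is a plain function and
#'   fully injectable, so the whole client is testable offline.
#' @name wp-client
NULL

#' Create a cancellation token
#'
#' An observable, sticky flag: once cancelled it can never be un-cancelled.
#'
#' @return An object of class `cancellation_token`.
#' @export
cancellation_token <- function() {
  env <- new.env(parent = emptyenv())
  env$cancelled <- FALSE
  structure(env, class = "cancellation_token")
}

#' Cancel a token
#' @param token A [cancellation_token()].
#' @return The token, invisibly.
#' @export
cancel <- function(token) {
  stopifnot(inherits(token, "cancellation_token"))
  token$cancelled <- TRUE
  invisible(token)
}

#' Has a token been cancelled?
#' @param token A [cancellation_token()], or `NULL` (never cancelled).
#' @return Logical flag.
#' @export
is_cancelled <- function(token) {
  if (is.null(token)) return(FALSE)
  isTRUE(token$cancelled)
}

# classed conditions so callers can distinguish outcomes
.cancelled_condition <- function(msg = "operation cancelled") {
  structure(class = c("gpml_cancelled", "error", "condition"),
            list(message = msg, call = NULL))
}
.transport_error <- function(msg) {
  structure(class = c("gpml_transport_error", "error", "condition"),
            list(message = msg, call = NULL))
}
.service_error <- function(status, msg = NULL) {
  structure(class = c(if (identical(status, 404L)) "gpml_not_found",
                      "gpml_service_error", "error", "condition"),
            list(message = msg %||% sprintf("service returned HTTP %d", status),
                 status = status, call = NULL))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Web-service client configuration
#'
#' Endpoint paths are configuration, not code: the REST API has moved over
#' the years, so the templates below (with `{query}`, `{organism}`,
#' `{wpid}`, `{revision}` placeholders) can be repointed freely.
#'
#' @param base_url Service base URL.
#' @param timeout_seconds Request timeout.
#' @param cache_dir Directory for the on-disk GPML cache, or `NULL` to
#'   disable caching.
#' @param search_path,gpml_path,organisms_path URL path templates appended
#'   to `base_url`.
#' @return An object of class `wp_config`.
#' @export
wp_config <- function(base_url = "https://webservice.wikipathways.org",
                      timeout_seconds = 30, cache_dir = NULL,
                      search_path = "/findPathwaysByText?query={query}&species={organism}&format=json",
                      gpml_path = "/getPathwayAs?fileType=gpml&pwId={wpid}&revision={revision}&format=xml",
                      organisms_path = "/listOrganisms?format=json") {
  structure(list(base_url = sub("/+$", "", base_url),
                 timeout_seconds = as.numeric(timeout_seconds),
                 cache_dir = cache_dir, search_path = search_path,
                 gpml_path = gpml_path, organisms_path = organisms_path),
            class = "wp_config")
}

#' Read a key=value client configuration file
#'
#' Recognized keys: `base_url`, `timeout_seconds`, `cache_dir`,
#' `search_path`, `gpml_path`, `organisms_path`; `#` comments allowed.
#'
#' @param path Config file path.
#' @return A [wp_config()].
#' @export
read_wp_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  args <- kv[intersect(names(kv), names(formals(wp_config)))]
  if (!is.null(args$timeout_seconds)) args$timeout_seconds <- as.numeric(args$timeout_seconds)
  do.call(wp_config, args)
}

.fill_template <- function(template, values) {
  for (nm in names(values))
    template <- gsub(paste0("{", nm, "}"), curl::curl_escape(values[[nm]] %||% ""),
                     template, fixed = TRUE)
  template
}

#' Default HTTP transport with mid-request abort
#'
#' Fetches a URL with curl, polling the cancellation token from the
#' progress callback; when the token fires the transfer is aborted and a
#' cancelled condition is signalled. Alternative transports (mocks, file
#' readers) are plain functions with the same signature.
#'
#' @param url URL to fetch.
#' @param token A [cancellation_token()] or `NULL`.
#' @param timeout_seconds Transfer timeout.
#' @return A list with `status_code` (integer) and `text` (response body).
#' @export
curl_transport <- function(url, token = NULL, timeout_seconds = 30) {
  if (is_cancelled(token)) stop(.cancelled_condition())
  h <- curl::new_handle(timeout = timeout_seconds, noprogress = FALSE,
                        progressfunction = function(down, up) {
                          # FALSE aborts the transfer
                          !is_cancelled(token)
                        })
  res <- tryCatch(curl::curl_fetch_memory(url, handle = h), error = function(e) e)
  if (inherits(res, "error")) {
    if (is_cancelled(token)) stop(.cancelled_condition())
    stop(.transport_error(conditionMessage(res)))
  }
  if (is_cancelled(token)) stop(.cancelled_condition())
  list(status_code = as.integer(res$status_code),
       text = rawToChar(res$content))
}

.do_request <- function(url, token, config, transport) {
  if (is_cancelled(token)) stop(.cancelled_condition())
  res <- tryCatch(
    transport(url, token, config$timeout_seconds),
    error = function(e) {
      if (inherits(e, c("gpml_cancelled", "gpml_service_error",
                        "gpml_transport_error", "gpml_not_found")))
        stop(e)
      # a cancelled token takes precedence over whatever the abort raised
      if (is_cancelled(token)) stop(.cancelled_condition())
      stop(.transport_error(conditionMessage(e)))
    })
  if (is_cancelled(token)) stop(.cancelled_condition())
  if (!is.list(res) || is.null(res$status_code))
    stop(.transport_error("transport returned no status code"))
  if (res$status_code >= 400L) stop(.service_error(as.integer(res$status_code)))
  res
}

#' Search pathways by free-text query
#'
#' @param query Non-empty query string.
#' @param organism Optional organism filter.
#' @param token Optional [cancellation_token()]; a pre-cancelled token
#'   raises a cancelled condition before any network call.
#' @param config A [wp_config()].
#' @param transport Transport function; defaults to [curl_transport()].
#' @return Data frame of pathway references: `wpid`, `name`, `organism`,
#'   `revision`. Zero rows on no hits. Entries whose id does not match
#'   `WP<digits>` are dropped with a warning.
#' @export
find_pathways <- function(query, organism = NULL, token = NULL,
                          config = wp_config(), transport = curl_transport) {
  stopifnot(nzchar(query))
  url <- paste0(config$base_url,
                .fill_template(config$search_path,
                               list(query = query, organism = organism)))
  res <- .do_request(url, token, config, transport)
  parsed <- tryCatch(jsonlite::fromJSON(res$text, simplifyVector = FALSE),
                     error = function(e)
                       stop(.service_error(200L, paste("unparseable search response:",
                                                       conditionMessage(e)))))
  hits <- parsed$result %||% list()
  refs <- lapply(hits, function(h)
    data.frame(wpid = as.character(h$id %||% ""),
               name = as.character(h$name %||% ""),
               organism = as.character(h$species %||% ""),
               revision = as.character(h$revision %||% ""),
               stringsAsFactors = FALSE))
  out <- if (length(refs) == 0)
    data.frame(wpid = character(0), name = character(0), organism = character(0),
               revision = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, refs)
  ok <- grepl("^WP\\d+$", out$wpid)
  if (any(!ok)) warning("dropping ", sum(!ok), " result(s) with malformed pathway id",
                        call. = FALSE)
  out[ok, , drop = FALSE]
}

.cache_path <- function(config, wpid, revision) {
  if (is.null(config$cache_dir)) return(NULL)
  file.path(config$cache_dir,
            sprintf("%s_%s.gpml", wpid, if (is.null(revision)) "latest" else revision))
}

#' Download a pathway's GPML
#'
#' The response is cached on disk keyed by (wpid, revision) when
#' `config$cache_dir` is set; the cache is written atomically only after a
#' complete, successful transfer, so cancellation never leaves a partial
#' entry.
#'
#' @param wpid Pathway id matching `WP<digits>`.
#' @param revision Optional revision string.
#' @param token Optional [cancellation_token()].
#' @param config A [wp_config()].
#' @param transport Transport function.
#' @param use_cache Read/write the on-disk cache? Default `TRUE`.
#' @return GPML text (accepted by [parse_gpml()]).
#' @export
get_pathway_gpml <- function(wpid, revision = NULL, token = NULL,
                             config = wp_config(), transport = curl_transport,
                             use_cache = TRUE) {
  if (!grepl("^WP\\d+$", wpid))
    stop("malformed pathway id '", wpid, "': expected WP<digits>", call. = FALSE)
  cp <- .cache_path(config, wpid, revision)
  if (use_cache && !is.null(cp) && file.exists(cp))
    return(paste(readLines(cp, warn = FALSE, encoding = "UTF-8"), collapse = "\n"))

  url <- paste0(config$base_url,
                .fill_template(config$gpml_path,
                               list(wpid = wpid, revision = revision %||% "0")))
  res <- .do_request(url, token, config, transport)
  txt <- res$text
  if (!grepl("<Pathway", txt, fixed = TRUE))
    stop(.service_error(as.integer(res$status_code), "response does not contain GPML"))
  if (use_cache && !is.null(cp)) {
    dir.create(dirname(cp), recursive = TRUE, showWarnings = FALSE)
    tmp <- paste0(cp, ".tmp")
    writeLines(txt, tmp, useBytes = TRUE)
    file.rename(tmp, cp)
  }
  txt
}

#' List organisms known to the service
#'
#' @inheritParams find_pathways
#' @return Character vector of organism names.
#' @export
list_organisms <- function(token = NULL, config = wp_config(),
                           transport = curl_transport) {
  url <- paste0(config$base_url, config$organisms_path)
  res <- .do_request(url, token, config, transport)
  parsed <- tryCatch(jsonlite::fromJSON(res$text, simplifyVector = TRUE),
                     error = function(e)
                       stop(.service_error(200L, "unparseable organism list")))
  as.character(parsed$organisms %||% character(0))
}
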