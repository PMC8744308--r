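# Readers/writers for the plain-text exchange formats: minimal GeoJSON
# (Point / LineString FeatureCollections), long-form travel-time CSV,
# contracts CSV with packed share maps, and YAML scenario configs.

#' Write a street network as GeoJSON
#'
#' Nodes become Point features (property `node_id`), edges LineString
#' features (properties `from`, `to`, `length_m`). Coordinates are planar
#' meters, not lon/lat.
#'
#' @param net a [street_network()].
#' @param path output file.
#' @export
write_network_geojson <- function(net, path) {
  node_feats <- lapply(seq_len(nrow(net$nodes)), function(i) {
    list(
      type = "Feature",
      geometry = list(
        type = "Point",
        coordinates = c(net$nodes$x[i], net$nodes$y[i])
      ),
      properties = list(node_id = net$nodes$node_id[i])
    )
  })
  xy <- function(id) {
    j <- match(id, net$nodes$node_id)
    c(net$nodes$x[j], net$nodes$y[j])
  }
  edge_feats <- lapply(seq_len(nrow(net$edges)), function(i) {
    list(
      type = "Feature",
      geometry = list(
        type = "LineString",
        coordinates = list(xy(net$edges$from[i]), xy(net$edges$to[i]))
      ),
      properties = list(
        from = net$edges$from[i],
        to = net$edges$to[i],
        length_m = net$edges$length_m[i]
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = c(node_feats, edge_feats))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
}

#' Read a street network from GeoJSON written by [write_network_geojson()]
#'
#' @param path GeoJSON file.
#' @return a [street_network()].
#' @export
read_network_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  is_point <- vapply(fc$features, function(f) f$geometry$type == "Point", logical(1))
  nodes <- do.call(rbind, lapply(fc$features[is_point], function(f) {
    tibble::tibble(
      node_id = as.integer(f$properties$node_id),
      x = as.numeric(f$geometry$coordinates[[1]]),
      y = as.numeric(f$geometry$coordinates[[2]])
    )
  }))
  edges <- do.call(rbind, lapply(fc$features[!is_point], function(f) {
    tibble::tibble(
      from = as.integer(f$properties$from),
      to = as.integer(f$properties$to),
      length_m = as.numeric(f$properties$length_m)
    )
  }))
  if (is.null(edges)) {
    edges <- tibble::tibble(from = integer(), to = integer(), length_m = numeric())
  }
  street_network(nodes, edges)
}

#' Write a point table (blocks, sites) as a GeoJSON FeatureCollection
#'
#' Every column other than `x`/`y` becomes a feature property.
#'
#' @param df data frame with `x` and `y` columns in planar meters.
#' @param path output file.
#' @export
write_points_geojson <- function(df, path) {
  stopifnot(all(c("x", "y") %in% names(df)))
  prop_cols <- setdiff(names(df), c("x", "y"))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, prop_cols, drop = FALSE])
    props <- props[!vapply(props, function(v) is.list(v) || all(is.na(v)), logical(1))]
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(df$x[i], df$y[i])),
      properties = props
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
}

#' Read a Point FeatureCollection into a tibble
#'
#' @param path GeoJSON file of Point features.
#' @return tibble with `x`, `y` and one column per property.
#' @export
read_points_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- lapply(fc$features, function(f) {
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    tibble::as_tibble(c(
      props,
      list(
        x = as.numeric(f$geometry$coordinates[[1]]),
        y = as.numeric(f$geometry$coordinates[[2]])
      )
    ))
  })
  do.call(rbind, rows)
}

#' Write a travel-time matrix as long-form CSV
#'
#' Columns: `origin_id`, `dest_id`, `minutes` (empty for unreachable
#' pairs), `reachable`.
#'
#' @param tt a `travel_time_matrix`.
#' @param path output file; a `.gz` suffix writes gzip-compressed.
#' @export
write_travel_csv <- function(tt, path) {
  fin <- is.finite(tt$minutes)
  long <- data.frame(
    origin_id = rep(tt$origin_ids, times = ncol(tt$minutes)),
    dest_id = rep(tt$dest_ids, each = nrow(tt$minutes)),
    minutes = as.vector(ifelse(fin, tt$minutes, NA)),
    reachable = as.vector(fin)
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  utils::write.csv(long, con, row.names = FALSE)
}

#' Read a long-form travel-time CSV back into a matrix
#'
#' @param path file written by [write_travel_csv()].
#' @return a `travel_time_matrix` (unreachable pairs as `Inf`).
#' @export
read_travel_csv <- function(path) {
  long <- utils::read.csv(path)
  o <- unique(long$origin_id)
  d <- unique(long$dest_id)
  minutes <- matrix(
    Inf, length(o), length(d),
    dimnames = list(as.character(o), as.character(d))
  )
  ok <- long$reachable
  minutes[cbind(match(long$origin_id[ok], o), match(long$dest_id[ok], d))] <-
    long$minutes[ok]
  travel_matrix(minutes, o, d)
}

#' Write contracts as CSV
#'
#' The `site_shares` list-column is packed as `site:share` pairs separated
#' by `;` (empty when unspecified).
#'
#' @param contracts contract tibble.
#' @param path output file.
#' @export
write_contracts_csv <- function(contracts, path) {
  packed <- vapply(contracts$site_shares, function(sh) {
    if (is.null(sh)) "" else paste(sprintf("%s:%.12g", names(sh), sh), collapse = ";")
  }, character(1))
  df <- contracts[setdiff(names(contracts), "site_shares")]
  df$site_shares <- packed
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read contracts from CSV written by [write_contracts_csv()]
#'
#' @param path CSV file.
#' @return contract tibble with a `site_shares` list-column.
#' @export
read_contracts_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  packed <- as.character(df$site_shares)
  packed[is.na(packed)] <- ""
  df$site_shares <- lapply(packed, function(s) {
    if (!nzchar(s)) return(NULL)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(
      vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
      vapply(parts, `[`, character(1), 1)
    )
  })
  df
}

#' Write / read a scenario configuration as YAML
#'
#' @param config a [scenario_config()].
#' @param path YAML file.
#' @export
write_config_yaml <- function(config, path) {
  cfg <- unclass(config)
  cfg$program_mix <- as.list(cfg$program_mix)  # keep names as a YAML map
  yaml::write_yaml(cfg, path)
}

#' @rdname write_config_yaml
#' @return `read_config_yaml()`: a validated `scenario_config`.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$program_mix)) raw$program_mix <- unlist(raw$program_mix)
  do.call(scenario_config, raw)
}
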