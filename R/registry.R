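#' Country name / ISO alpha-3 registry
#'
#' A small bundled registry mapping country names (including common variants)
#' to ISO 3166-1 alpha-3 codes for the coastal African countries ranked by
#' this package and the Asian / Arabian source-population countries. Input
#' tables may use either names or codes; [to_country_code()] canonicalizes
#' both.
#'
#' @return A data frame with columns `name` and `code`.
#' @export
#' @examples
#' head(country_registry())
country_registry <- function() {
  reg <- c(
    "Algeria" = "DZA", "Angola" = "AGO", "Benin" = "BEN",
    "Cameroon" = "CMR", "Cabo Verde" = "CPV", "Cape Verde" = "CPV",
    "Comoros" = "COM", "Congo" = "COG", "Republic of the Congo" = "COG",
    "Democratic Republic of the Congo" = "COD", "DR Congo" = "COD",
    "Cote d'Ivoire" = "CIV", "Ivory Coast" = "CIV",
    "Djibouti" = "DJI", "Egypt" = "EGY", "Equatorial Guinea" = "GNQ",
    "Eritrea" = "ERI", "Gabon" = "GAB", "Gambia" = "GMB", "Ghana" = "GHA",
    "Guinea" = "GIN", "Guinea-Bissau" = "GNB", "Kenya" = "KEN",
    "Liberia" = "LBR", "Libya" = "LBY", "Madagascar" = "MDG",
    "Mauritania" = "MRT", "Mauritius" = "MUS", "Morocco" = "MAR",
    "Mozambique" = "MOZ", "Namibia" = "NAM", "Nigeria" = "NGA",
    "Sao Tome and Principe" = "STP", "Senegal" = "SEN",
    "Seychelles" = "SYC", "Sierra Leone" = "SLE", "Somalia" = "SOM",
    "South Africa" = "ZAF", "Sudan" = "SDN", "Tanzania" = "TZA",
    "United Republic of Tanzania" = "TZA", "Togo" = "TGO",
    "Tunisia" = "TUN",
    # source-population countries
    "India" = "IND", "Pakistan" = "PAK", "Saudi Arabia" = "SAU",
    "United Arab Emirates" = "ARE", "UAE" = "ARE",
    "Iran" = "IRN", "Iraq" = "IRQ", "Myanmar" = "MMR", "Thailand" = "THA"
  )
  data.frame(name = names(reg), code = unname(reg), stringsAsFactors = FALSE)
}

#' Canonicalize country identifiers to ISO alpha-3 codes
#'
#' Accepts either three-character codes (any case; ISO alpha-3 for real
#' countries, alphanumeric for synthetic ones) or country names known to the
#' bundled registry. Unknown names, and strings that are neither a
#' three-character code nor a registry name, are a hard error: silently
#' dropping a country would corrupt every downstream ranking.
#'
#' @param x Character vector of country names or alpha-3 codes.
#' @return Character vector of uppercase alpha-3 codes.
#' @export
#' @examples
#' to_country_code(c("Djibouti", "sdn", "Kenya"))
to_country_code <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  x <- trimws(x)
  reg <- country_registry()
  # registry names take precedence ("UAE" is a name variant, not a code)
  idx <- match(toupper(x), toupper(reg$name))
  out <- reg$code[idx]
  unknown <- is.na(idx)
  is_code <- unknown & grepl("^[A-Za-z0-9]{3}$", x)
  out[is_code] <- toupper(x[is_code])
  if (any(unknown & !is_code)) {
    bad <- unique(x[unknown & !is_code])
    stop("unknown country name(s): ", paste(bad, collapse = ", "),
         " (not in the bundled registry and not a 3-character code)",
         call. = FALSE)
  }
  out
}
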