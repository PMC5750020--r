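# the classic six-language Germanic illustration used across several tests
germanic <- function() {
  classification(
    c("English", "German", "Dutch", "Icelandic", "Norwegian", "Swedish"),
    list(c("Germanic", "West"), c("Germanic", "West", "Continental"),
         c("Germanic", "West", "Continental"), c("Germanic", "North"),
         c("Germanic", "North"), c("Germanic", "North")))
}
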