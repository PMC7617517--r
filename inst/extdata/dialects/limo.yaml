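device: "LIMO"
manufacturer: "Ecole nationale des travaux publics de l'Etat (ENTPE)"
delimiter: ","
skip: 0
header: true
decimal_mark: "."
datetime:
  columns: ["datetime"]
  format: "%Y/%m/%d %H:%M:%S"
  timezone: supplied
id_column: null
channels:
  - column: "EDI"
    channel: "MEDI"
    unit: "mel-EDI lx"
  - column: "illuminance"
    channel: "lux"
    unit: "lx"
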