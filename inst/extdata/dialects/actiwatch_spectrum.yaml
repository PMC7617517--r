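device: "Actiwatch Spectrum"
manufacturer: "Philips Respironics"
delimiter: ","
skip: 0
header: true
decimal_mark: "."
datetime:
  columns: ["Date", "Time"]
  format: ["%m/%d/%Y", "%I:%M:%S %p"]
  timezone: supplied
id_column: null
channels:
  - column: "White Light"
    channel: "lux"
    unit: "lx"
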