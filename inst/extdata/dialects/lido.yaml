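device: "Lido"
manufacturer: "Lucerne University of Applied Sciences and Arts"
delimiter: ";"
skip: 0
header: true
decimal_mark: "."
datetime:
  columns: ["UTC Timestamp"]
  format: "%Y-%m-%dT%H:%M:%S%z"
  timezone: embedded
id_column: null
channels:
  - column: "Illuminance"
    channel: "lux"
    unit: "lx"
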