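# Metadata extraction mapping: which source fields are collected into the
# JSON sidecar during conversion. Edit or copy this file and pass it to the
# converter to customize the collected metadata.
#
# Each rule binds one sidecar key (target_key) to a source address in one
# dialect. For DICOM the address is a "(group,element)" tag. unit_conversion
# multiplies numeric values; times are kept in milliseconds (DICOM native),
# so the factor is 1.
rules:
  - target_key: Modality
    source_dialect: dicom
    source_address: "(0008,0060)"
    unit_conversion: 1
  - target_key: EchoTime
    source_dialect: dicom
    source_address: "(0018,0081)"
    unit_conversion: 1
  - target_key: RepetitionTime
    source_dialect: dicom
    source_address: "(0018,0080)"
    unit_conversion: 1
  - target_key: FlipAngle
    source_dialect: dicom
    source_address: "(0018,1314)"
    unit_conversion: 1
  - target_key: AcquisitionDateTime
    source_dialect: dicom
    source_address: "(0008,002A)"
    unit_conversion: 1
  - target_key: SeriesDescription
    source_dialect: dicom
    source_address: "(0008,103E)"
    unit_conversion: 1
  - target_key: SliceThickness
    source_dialect: dicom
    source_address: "(0018,0050)"
    unit_conversion: 1
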