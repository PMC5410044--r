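gene: BRAFlike
chrom: chrS
strand: '-'
exons:
- id: E1
  start: 1399701
  end: 1400000
- id: E2
  start: 1398681
  end: 1398800
- id: E3
  start: 1397331
  end: 1397480
- id: E4
  start: 1395996
  end: 1396130
- id: E5
  start: 1395094
  end: 1395195
- id: E6
  start: 1394274
  end: 1394393
- id: E7
  start: 1393536
  end: 1393673
- id: E8
  start: 1392525
  end: 1392635
- id: E9
  start: 1391899
  end: 1392024
- id: E10
  start: 1391055
  end: 1391198
- id: E11
  start: 1389938
  end: 1390054
- id: E12
  start: 1389230
  end: 1389337
- id: E13
  start: 1388298
  end: 1388429
- id: E14
  start: 1387521
  end: 1387697
- id: E15
  start: 1386805
  end: 1387020
- id: E16
  start: 1385982
  end: 1386104
- id: E17
  start: 1385429
  end: 1385581
- id: E18.1
  start: 1383670
  end: 1384428
- id: E18.2
  start: 1384275
  end: 1384428
- id: E18.3
  start: 1384179
  end: 1384428
- id: E18.4
  start: 1384137
  end: 1384428
- id: E18.5
  start: 1384255
  end: 1384428
- id: E19
  start: 1372670
  end: 1379669
- id: NE6
  start: 1396783
  end: 1397480
- id: NE1
  start: 1390605
  end: 1390754
- id: NE2
  start: 1389588
  end: 1389737
- id: NE3
  start: 1388780
  end: 1388929
- id: NE4
  start: 1387948
  end: 1388097
- id: NE5
  start: 1399251
  end: 1399400
- id: E18b
  start: 1384179
  end: 1384274
- id: NE6p
  start: 1396783
  end: 1397330
transcripts:
- id: ref
  exons:
  - E1
  - E2
  - E3
  - E4
  - E5
  - E6
  - E7
  - E8
  - E9
  - E10
  - E11
  - E12
  - E13
  - E14
  - E15
  - E16
  - E17
  - E18.3
  cds_end_tx: 2646
- id: X1
  exons:
  - E1
  - E2
  - E3
  - E4
  - E5
  - E6
  - E7
  - E8
  - E9
  - E10
  - E11
  - E12
  - E13
  - E14
  - E15
  - E16
  - E17
  - E18.2
  - E19
  cds_end_tx: 2926
- id: X2
  exons:
  - E1
  - E2
  - E3
  - E4
  - E5
  - E6
  - E7
  - E8
  - E9
  - E10
  - E11
  - E12
  - E13
  - E14
  - E15
  - E16
  - E17
  - E19
  cds_end_tx: 2822
- id: '004'
  exons:
  - E1
  - E2
  - NE6
  cds_end_tx: ~
- id: 004rt
  exons:
  - E1
  - E2
  - NE6
  - E4
  - E5
  - E6
  cds_end_tx: ~
- id: X7
  exons:
  - E1
  - E2
  - E3
  - E4
  - E5
  - E6
  - E7
  - E8
  - E9
  - E10
  - E11
  - E12
  - E13
  - E16
  - E17
  - E18.3
  cds_end_tx: ~
- id: delta310-ref
  exons:
  - E1
  - E2
  - E11
  - E12
  - E13
  - E14
  - E15
  - E16
  - E17
  - E18.3
  cds_end_tx: ~
- id: delta310-X1
  exons:
  - E1
  - E2
  - E11
  - E12
  - E13
  - E14
  - E15
  - E16
  - E17
  - E18.2
  - E19
  cds_end_tx: ~
- id: delta310-X2
  exons:
  - E1
  - E2
  - E11
  - E12
  - E13
  - E14
  - E15
  - E16
  - E17
  - E19
  cds_end_tx: ~
junctions:
- id: E17-E18.2
  donor: E17
  acceptor: E18.2
  measure: ref+X1
  absence_probe: no
- id: E18.2-E18b
  donor: E18.2
  acceptor: E18b
  measure: ref
  absence_probe: no
- id: E18.2-E19
  donor: E18.2
  acceptor: E19
  measure: X1
  absence_probe: no
- id: E17-E19
  donor: E17
  acceptor: E19
  measure: X2
  absence_probe: no
- id: E2-E3
  donor: E2
  acceptor: E3
  measure: fl
  absence_probe: no
- id: E2-E11
  donor: E2
  acceptor: E11
  measure: delta310
  absence_probe: no
- id: E13-E16
  donor: E13
  acceptor: E16
  measure: X7
  absence_probe: yes
- id: NE6p-E4
  donor: NE6p
  acceptor: E4
  measure: 004rt
  absence_probe: yes
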