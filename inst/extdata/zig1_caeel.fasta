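>G5EGI7 ZIG1_CAEEL
MKNLLLITFFVVSTVTALGGRGSKSALVLVAARSSENHPLHATDPITIWCAPDNPQVVIK
TAHFIRSSDNEKLEAALNPTKKNATYTFGSPSVKDAGEYKCELDTPHGKISHKVFIYSRP
VVHSHEHFTEHEGHEFHLESTGTTVEKGESVTLTCPVTGYPKPVVKWTKDSAPLALSQSV
SMEGSTVIVTNANYTDAGTYSCEAVNEYTVNGKTSKMLLVVDKMVDVRSEFQWVYPLAVI
LITIFLLVVIIVFCEWRNKKSTSKA
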