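stratum,regimen,percent,ci_low,ci_high,n_stratum
minimal,NK1RA+5HT3RA+steroid,0.6,0.2,1.1,1451
minimal,5HT3RA+steroid,3.2,2.4,4.3,1451
minimal,NK1RA+5HT3RA,3.0,2.0,4.0,1451
minimal,NK1RA,0.3,0.1,0.8,1451
minimal,5HT3RA,37.8,35.0,40.0,1451
minimal,steroid,3.4,2.0,4.0,1451
minimal,none,51.6,49.0,54.2,1451
low,NK1RA+5HT3RA+steroid,1.5,1.2,1.8,5806
low,5HT3RA+steroid,9.4,8.7,10.2,5806
low,NK1RA+5HT3RA,2.6,2.2,3.0,5806
low,NK1RA+steroid,0.2,0.1,0.3,5806
low,NK1RA,0.2,0.1,0.3,5806
low,5HT3RA,52.0,50.7,53.3,5806
low,steroid,5.9,5.3,6.6,5806
low,none,28.3,27.1,29.4,5806
moderate,NK1RA+5HT3RA+steroid,14.0,13.2,14.8,7188
moderate,NK1RA+steroid,0.1,0.0,0.2,7188
moderate,NK1RA+5HT3RA,7.3,6.8,8.0,7188
moderate,5HT3RA+steroid,32.1,31.0,33.2,7188
moderate,NK1RA,0.2,0.1,0.3,7188
moderate,5HT3RA,43.0,41.9,44.2,7188
moderate,steroid,0.4,0.3,0.6,7188
moderate,none,2.9,2.5,3.3,7188
high_adult,NK1RA+5HT3RA+steroid,51.1,49.5,52.6,4130
high_adult,5HT3RA+steroid,20.1,18.9,21.4,4130
high_adult,NK1RA+5HT3RA,9.7,8.8,10.7,4130
high_adult,NK1RA+steroid,0.3,0.2,0.5,4130
high_adult,NK1RA,0.2,0.1,0.3,4130
high_adult,5HT3RA,17.6,16.5,18.8,4130
high_adult,steroid,0.3,0.2,0.5,4130
high_adult,none,0.7,0.5,1.0,4130
high_under18,NK1RA+5HT3RA+steroid,21.5,19.9,23.2,2531
high_under18,5HT3RA+steroid,18.2,16.7,19.8,2531
high_under18,NK1RA+5HT3RA,10.2,9.1,11.5,2531
high_under18,NK1RA+steroid,0.2,0.0,0.4,2531
high_under18,NK1RA,0.2,0.0,0.4,2531
high_under18,5HT3RA,48.2,46.2,50.1,2531
high_under18,steroid,0.2,0.1,0.5,2531
high_under18,none,1.3,0.9,1.9,2531
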