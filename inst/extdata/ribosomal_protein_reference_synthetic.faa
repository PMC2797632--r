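>rp_synth_1 synthetic ribosomal-protein stand-in
MFLTKSFASSVQRGTTMTYSCKGGPTIMMERCLLDEERTCLTIFFWPPIAMVCKPSFLSRKLSDSMSLTVLWTSPQSGRLNTECGEGDTSGMIIHILLCRRPGTASSPRLVGRLLSRYSSMAYLILIEHAAEKTSDLFTEVHLEIVLVGRATLVRFRSGEISESGEHLLHPTGVYRSSEFCWLVTHLGGTALRDLATTPHPDRGCTLHRTRGMVPTSRCLRHISTATPLTVSHHSGTVQVNIPLVFTTLWLTRLPQHYTSVPSSTRRIPRVIFSLMDNGHDEQVHKFCTPVSTRSWEGSRLFDPVCSSILSGYQAWHEVESRYKIASHASPLFAWLLASISSHHRESDTNYYEISTRIASH
>rp_synth_2 synthetic ribosomal-protein stand-in
MQPPLVDLRQSIPNQPVAQVSPSLSSKTGPGTRPGHDCVLRAFLLVDVASRHHSIHGRVLRLGYRSVFLVALRAVYTLATFRTLLKNRPHALARKISRYYGWIYLERQATTVGNLSSPVASRGRRVTMAYRKGYRGKRRCFAPQKGHKYDWTLIYRHETRDHVSVYHRLIYHYNTLPSGHTDFAMLNAIWDTAGAFWSYLWVSFLYNHTIPGIANYHGSDVSVTLGREILVDRSPSLGVVPHALITLLLMECLALRNETPDRHGWRNGVTFAAP
>rp_synth_3 synthetic ribosomal-protein stand-in
MMSWPVRQGKLPVSPIICPIDPSHTQKLGFEPVIRSTPASPGLAELITYNLRNNPPIEISPGMRPVLGKQPSNLVKPSGPQRCVPLLLVVGYYLYAVHLPHCSCTSREAKPRRIARGRAPRTFCAQPRRRSFELVTSLYRVIQRETIPHQVGTLSGHTSGRLPQLDTFPLKRTLGSLRVDKPPPPSNNSRPRFTTAELPTTPRRFFGLRCCLCLLPLIHGVPSSRTARHYSTLPRWESTIVMPCKSQNIQRSSVSGSGPICFSGVPWLIRDRDAALVALSSLSLESHRSSSEHREWARIFLGLLSASVGRTVLPD
>rp_synth_4 synthetic ribosomal-protein stand-in
MRKVHLRLTEPKHSTTPKMGFLFRLGSNVLKYRVRVLRPNVAPCFRDGAQPRLSIDPMNRTYNRPRSYAHYSPFSQKSIKRPSACTTSSSSRRVWVETLRYSRDRMNRDCVRPYATINLARTISLRDRHTDYLLYITDRASPQISNLGSRIQHYHLEAMRDDPVFNTSPQRSSIPIQGLPSHAQPCRPREVPRSRQCVKLCLGFSRARLYKHFSLPSGALQSGLMLTRQRKVPTNWWAPFACPTAWGINQGMTTRPVARQSKRYSVRNSLCTQPSKHSLVWAVHSWVTPTSFLYVIVPYRRLPICGLTFQSAYYRANEIGSTSEGNS
>rp_synth_5 synthetic ribosomal-protein stand-in
MVWRSICGHLSDAIVRALTNVIHATSTCGGSGMVGFSDVAGYRYPRFICRQTLGPQLPATSVLDMRPLPDISDKVGSGVPPRTQAILTKATCTCCAKGPFSPLTARAAEQHSKKAATVRADLADLTHRGYIYLERGRFSGVIPQCMTLRIRPPNFVRICRQSVSFAFGMPHQDVEMRSTVVNGHLLKMPRLVILLQSQPAFDKSLPDEIFLGSSSFSPVIALEQPLDSCGFLLTDGYHLLRGSEERLELQRLFNINSEPPTFSSVQNTLGGSSRFVRTLGDRSRLGFVRWPRPGAPPVRRGFRWEPHNHHSNHRRTR
>rp_synth_6 synthetic ribosomal-protein stand-in
MKLGKLTGLRLPRLALLIPLYSSPGVSLSRRVLSWDPCLSQRPSRGISAVVSFQKACHFSHSDCPRSSVSPSERAGFSIEEALMGFPGLVGYGAIGDTGTSGYFFNFLYHPDISTVIPNFLTFRAMIRVLFSLTPEEKTSKQRPYEEEFSSVFLFTVSNRGLLSDAFNCQAGTNVQRCQSSLLDLCPRSVSKKVSHMRVWFVRNNFLVGLRSSRLSVMHVSSWRRAPTGLPRVLICLTLEGNNASPALVVLYLTFPGAATQLGLIQRIGCPFLPRSMLISQHNWRAWAHRRSSV
>rp_synth_7 synthetic ribosomal-protein stand-in
MTKLSAWRTVAFGFHLKLNSLVATALMLMWCLRGASATGNINALMKLLPVLFQRSGQRGPYPLRNVIMSSVSGRSYSILTRHRPSQLVIQNGSRQLQLFCLEFCLYAVSDNTFHHSIGYLAGQSVRASRSCPTARGAQHFIQKHVMSQHWQNYGRLLTHPTDTYPTVRHPLYSRWWVVLTKCVGSFVCGSQILRWSSGKQKPSVHGSEGGRTKLRSGLPSAYLVSLACVKIVTKSITYHAMLVVNDRMTQTDFGAGLLFAFLSQSLPEHLLRQAGNFGPSSPLPLVRPCARVSWYGQIEITDKFNTRTRGPRRKFCCWLSMLWQQLTVFRIVAGLKGTDISLDMQLIYHFPDICGSPRNSRLSYVIR
>rp_synth_8 synthetic ribosomal-protein stand-in
MKGPARTGVVVLINGHGFQPEYRCSQLETLRTKLDSRPGAGLVSIVITAPHRRQLRRRPSIFSTSGRSKKGQSALYNKDKVRSLERDIRQLVVLCSSKSLTDGPQKERVQTKEQIWTPVAIRSGQDIFRQNMESFHDNPVADRTSPLHLFLVRRLSTHGVKVSANLGTRPAYRSTTIIYTKLVYRVPRTPCNGQRAVPCTELDLSIEHCPHLRFLDKVSSERVFQYAPFCERRYVGICQKWGPHVHLLDTLISTSGKDKKADVSRIRATFRLALAARGINTIRDTSQIQYLRRIT
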