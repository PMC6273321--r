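formula,mass
C36H89NO13,743.633391913
C21H8NO5,354.040247359
C37H86O5,610.647525856
C40H22N3O12,736.120348155
C42H95N3O10,801.701746257
C23H31O13,515.176466048
C55H97N2O9,929.719407696
C1H70NO13,304.484716304
C58H89N2O6,909.672063581
C6H94NO10,340.687773215
C33H55O7,563.394779101
C47H31N2O9,767.202955580
C16H33N3O10,427.216594268
C50H12N3O15,894.026841693
C33H71N3O,525.559713911
C45H92O5,712.694476048
C57H24NO2,754.180704014
C54H39O15,927.228895544
C49H22N2O2,670.168127954
C5H42NO10,276.280871547
C33H87O7,595.645180127
C32H69N3O,511.544063847
C36H23O2,487.169804977
C19H98NO8,468.729244104
C49H42NO14,868.260530026
C24H62N2O15,618.415019291
C47H71O14,859.484381951
C36H81NO4,591.616560081
C53H96N2O2,792.747180327
C32H72NO9,614.520707890
C30H78NO6,548.582914224
C49H39N2O2,687.301153499
C43H57O9,717.400258404
C26H60NO11,562.416636744
C60H10NO13,952.015214380
C3H67O13,311.458167203
C54H70O8,846.507069201
C60H27N3O4,853.200156359
C21H77NO13,551.539491528
C4H12N2O2,120.089877634
C32H73N2O12,677.516350785
C46H60N3O6,750.448211656
C45H5N2O12,764.984248605
C19H1N2,257.013973042
C44H91NO6,729.684639641
C17H31N2O13,471.182614058
C11H20N3O14,418.094527330
C14H80N3O14,514.564029254
C37H23N3O15,749.112917045
C36H23NO8,597.142366699
C56H17N3O9,875.096479136
C26H95O,423.738292666
C51H30O7,754.199153299
C52H7N2O6,755.030410951
C59H28O9,880.173332474
C47H44NO13,830.281265470
C45H85O5,705.639700824
C60H32NO2,798.243304270
C39H46N3O11,732.313234305
C34H45NO15,707.278919741
C52H43NO5,761.314123482
C60H64NO5,878.478449155
C45H17N3O13,807.076137614
C52H25N2O6,773.171261529
C57H36N3O7,874.255325506
C29H66O15,654.440171410
C17H27N2O10,419.166570071
C47H47O14,835.296581181
C8H39O13,343.239066305
C38H33NO7,615.225702400
C33N3O,454.004136634
C30H9N2O9,541.030804874
H75O11,251.530938220
C20H30O14,494.163555636
C54H77NO,755.600516094
C17H69N2O3,349.530819081
C45H30NO3,632.222568826
C18H29N3O13,495.170037999
C17H70N3O3,364.541718118
C20H62N2O5,410.465873096
C55H48NO12,914.317650979
C3H11N2O9,219.046454938
C43H42N3,600.337873361
C27H29O4,417.206584408
C57H52N3O15,1018.339842975
C52H23O9,791.134207314
C60H37N3O7,911.263150538
C52H20O8,772.115817598
C57H100N3O2,858.781554461
C42H40N2O2,604.308978532
C28H31N2O8,523.208040960
C36H99N3O4,637.763558668
C50H67O3,715.509021007
C12H94NO13,460.672517074
C25H1N3O4,406.996705525
C36H10O14,666.007054995
C19H30O,274.229665582
C20H88N2O2,388.684580071
C19H44N2O3,348.335193279
C30H47N3O8,577.336315478
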